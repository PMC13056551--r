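#' Fit the negative-binomial contamination null from negative controls
#'
#' Water controls sequenced alongside clinical samples carry the reagent
#' and environmental contamination background. Counts of each feature
#' (taxon or resistance gene) in the controls are modelled as negative
#' binomial with a separate mean for every batch:feature cell and a single
#' dispersion shared across all features: the cell means are the control
#' sample means, and the dispersion maximises the pooled profile
#' log-likelihood with the means held at those values.
#'
#' Cells whose control mean is zero put all null mass at zero; they are
#' excluded from the dispersion optimisation (their likelihood contribution
#' is a constant point mass) and handled downstream by the unseen-feature
#' rule of [apply_decontam()].
#'
#' @param control_counts Integer matrix, control samples x features (a
#'   `feature_table` of kind `"reads"` works).
#' @param batch Character vector, one batch label per control row.
#' @param theta_bounds Search interval for the dispersion (NB `size`); the
#'   fit reports when it lands on a boundary (the upper boundary is the
#'   Poisson limit reached when control counts show no excess variance).
#' @return A `decontam_null` object: `mu` (batch x feature mean matrix over
#'   the batches seen in controls), `theta`, `theta_boundary`,
#'   `n_controls` per batch.
#' @export
fit_null <- function(control_counts, batch, theta_bounds = c(1e-3, 1e6)) {
  mat <- unclass(control_counts)
  if (!is.matrix(mat)) stop("control_counts must be a matrix", call. = FALSE)
  if (length(batch) != nrow(mat)) {
    stop("batch must have one entry per control sample", call. = FALSE)
  }
  if (nrow(mat) < 2) stop("need at least 2 control samples", call. = FALSE)
  if (any(mat < 0) || any(mat != round(mat))) {
    stop("control counts must be non-negative integers", call. = FALSE)
  }
  if (all(mat == 0)) {
    stop("no contamination signal; theta undefined", call. = FALSE)
  }
  batches <- sort(unique(as.character(batch)))
  mu <- t(vapply(batches, function(b) {
    colMeans(mat[batch == b, , drop = FALSE])
  }, numeric(ncol(mat))))
  dimnames(mu) <- list(batches, colnames(mat))

  # Pooled profile log-likelihood in theta with cell means fixed.
  mu_per_obs <- mu[cbind(match(as.character(batch), batches),
                         rep(seq_len(ncol(mat)), each = nrow(mat)))]
  x <- as.vector(mat)
  keep <- mu_per_obs > 0
  x <- x[keep]
  mu_obs <- mu_per_obs[keep]
  loglik <- function(log_theta) {
    sum(stats::dnbinom(x, size = exp(log_theta), mu = mu_obs, log = TRUE))
  }
  opt <- stats::optimize(loglik, interval = log(theta_bounds), maximum = TRUE,
                         tol = 1e-8)
  theta <- exp(opt$maximum)
  boundary <- theta <= theta_bounds[1] * (1 + 1e-4) ||
    theta >= theta_bounds[2] * (1 - 1e-4)
  if (boundary) theta <- ifelse(theta > 1, theta_bounds[2], theta_bounds[1])
  structure(
    list(mu = mu, theta = theta, theta_boundary = boundary,
         theta_bounds = theta_bounds,
         n_controls = table(factor(as.character(batch), levels = batches))),
    class = "decontam_null"
  )
}

#' @export
print.decontam_null <- function(x, ...) {
  cat(sprintf("<decontam_null: %d batches, %d features, theta = %.4g%s>\n",
              nrow(x$mu), ncol(x$mu), x$theta,
              if (x$theta_boundary) " (boundary)" else ""))
  invisible(x)
}

#' Upper-tail probability of a negative-binomial contamination null
#'
#' Returns P(X >= x) for X ~ NB(mean `mu`, dispersion `theta`). A zero-mean
#' cell is a point mass at zero: any positive count has tail probability 0
#' and `x = 0` has tail probability 1.
#'
#' @param x Observed count (non-negative integer, vectorised).
#' @param mu Null mean (recycled).
#' @param theta Dispersion (NB `size` parameter), > 0.
#' @return Upper-tail p-values in \[0, 1\].
#' @export
tail_pvalue <- function(x, mu, theta) {
  if (any(x < 0) || any(x != round(x))) {
    stop("x must be a non-negative integer count", call. = FALSE)
  }
  if (any(mu < 0)) stop("mu must be >= 0", call. = FALSE)
  if (any(theta <= 0)) stop("theta must be > 0", call. = FALSE)
  n <- max(length(x), length(mu), length(theta))
  x <- rep_len(x, n); mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  p <- numeric(n)
  zero_mu <- mu == 0
  p[zero_mu] <- ifelse(x[zero_mu] > 0, 0, 1)
  idx <- !zero_mu
  # P(X >= x) = P(X > x - 1)
  p[idx] <- ifelse(x[idx] == 0, 1,
                   stats::pnbinom(x[idx] - 1, size = theta[idx], mu = mu[idx],
                                  lower.tail = FALSE))
  p
}

#' Remove background contamination from a sample table
#'
#' Tests every positive (sample, feature) count against the batch-matched
#' negative-binomial null and retains only features significantly above
#' background (Benjamini-Hochberg q below `fdr`). Features carried by a
#' sample but never seen in that batch's controls cannot be contamination
#' under the null (the null mass sits entirely at zero); they are retained
#' and flagged `unseen_in_controls` rather than entering the BH family,
#' which keeps degenerate zero p-values from distorting the adjustment.
#'
#' @param sample_table `feature_table` of raw counts (samples x features).
#' @param batch Character vector of batch labels, one per sample row.
#' @param null A `decontam_null` from [fit_null()].
#' @param fdr Retention threshold on the BH-adjusted q-value (default 0.1).
#' @param family `"per-sample"` (BH within each sample across its observed
#'   features; the default) or `"global"` (one family over all tested
#'   pairs).
#' @return List with `table` (the input with removed features zeroed) and
#'   `decisions`, a tibble of every tested or flagged pair: count, null
#'   mean, p, q, `retained`, `unseen_in_controls`.
#' @export
apply_decontam <- function(sample_table, batch, null, fdr = 0.1,
                           family = c("per-sample", "global")) {
  family <- match.arg(family)
  mat <- unclass(sample_table)
  if (length(batch) != nrow(mat)) {
    stop("batch must have one entry per sample row", call. = FALSE)
  }
  unknown <- setdiff(unique(as.character(batch)), rownames(null$mu))
  if (length(unknown) > 0) {
    stop("batch(es) not covered by the null model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pos <- which(mat > 0, arr.ind = TRUE)
  feat <- colnames(mat)[pos[, 2]]
  # Features absent from the control panel entirely behave like mu = 0.
  mu_vec <- rep(0, nrow(pos))
  known_feat <- feat %in% colnames(null$mu)
  if (any(known_feat)) {
    mu_vec[known_feat] <- null$mu[cbind(
      match(as.character(batch)[pos[known_feat, 1]], rownames(null$mu)),
      match(feat[known_feat], colnames(null$mu))
    )]
  }
  counts <- mat[pos]
  p <- tail_pvalue(counts, mu_vec, null$theta)
  unseen <- mu_vec == 0
  decisions <- tibble::tibble(
    sample_id = rownames(mat)[pos[, 1]],
    feature = feat,
    batch = as.character(batch)[pos[, 1]],
    count = counts,
    mu = mu_vec,
    theta = null$theta,
    p = p,
    q = NA_real_,
    unseen_in_controls = unseen,
    retained = NA
  )
  tested <- !unseen
  if (any(tested)) {
    if (family == "per-sample") {
      decisions$q[tested] <- stats::ave(
        decisions$p[tested], decisions$sample_id[tested],
        FUN = function(v) stats::p.adjust(v, method = "BH")
      )
    } else {
      decisions$q[tested] <- stats::p.adjust(decisions$p[tested], method = "BH")
    }
  }
  decisions$retained <- unseen | (!is.na(decisions$q) & decisions$q < fdr)
  out <- mat
  drop <- decisions[!decisions$retained, , drop = FALSE]
  if (nrow(drop) > 0) {
    out[cbind(match(drop$sample_id, rownames(out)),
              match(drop$feature, colnames(out)))] <- 0
  }
  list(table = feature_table(out, value_kind(sample_table) %||% "reads"),
       decisions = decisions, fdr = fdr, family = family)
}
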