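#' Shannon diversity index
#'
#' H = -sum p_i log p_i over the relative abundances p_i = x_i / sum(x),
#' with zero entries contributing nothing. Natural log by default (the
#' convention of the standard community-ecology implementations); `base`
#' switches, e.g. to 2.
#'
#' @param x Non-negative abundance vector with at least one positive entry.
#' @param base Logarithm base; default `exp(1)` (nats).
#' @return Shannon index H.
#' @export
#' @examples
#' shannon(rep(1, 8)) # log(8)
shannon <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(x)
  if (tot <= 0) stop("all-zero abundance vector", call. = FALSE)
  p <- x[x > 0] / tot
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' d(u, v) = sum |u_i - v_i| / sum (u_i + v_i).
#'
#' @param u,v Non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length", call. = FALSE)
  if (any(u < 0) || any(v < 0)) stop("abundances must be non-negative", call. = FALSE)
  denom <- sum(u + v)
  if (denom == 0) stop("both profiles are all-zero", call. = FALSE)
  sum(abs(u - v)) / denom
}

#' Bray-Curtis distance matrix for an abundance table
#'
#' @param tab Samples x features abundance matrix (or `feature_table`);
#'   every sample must have positive total abundance.
#' @return Square symmetric matrix with sample dimnames, zero diagonal,
#'   values in \[0, 1\].
#' @export
bray_curtis_matrix <- function(tab) {
  mat <- unclass(tab)
  if (any(rowSums(mat) == 0)) {
    stop("sample(s) with all-zero profiles: ",
         paste(rownames(mat)[rowSums(mat) == 0], collapse = ", "), call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(mat, method = "bray"))
  validate_distance_matrix(d)
}

#' Validate a dissimilarity matrix
#'
#' Checks squareness, zero diagonal, symmetry (to 1e-12) and the \[0, 1\]
#' range expected of Bray-Curtis dissimilarities.
#'
#' @param d Square numeric matrix with sample dimnames.
#' @return `d` unchanged.
#' @export
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("not a square matrix", call. = FALSE)
  if (max(abs(diag(d))) > 1e-12) stop("non-zero diagonal", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("asymmetric dissimilarity matrix", call. = FALSE)
  if (any(d < -1e-12) || any(d > 1 + 1e-12)) stop("values outside [0, 1]", call. = FALSE)
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres -D^2/2, eigendecomposes, and returns the top-k
#' coordinates scaled by the square root of their eigenvalues. Negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are dropped and reported. For a Euclidean distance matrix
#' the full-rank embedding reproduces the input distances.
#'
#' @param d Distance matrix (validated by [validate_distance_matrix()]
#'   conventions; any symmetric zero-diagonal matrix is accepted).
#' @param k Number of coordinate axes requested; truncated with a warning
#'   when it exceeds the number of positive eigenvalues.
#' @return List with `coords` (samples x k), `eigenvalues` (positive, in
#'   decreasing order), `negative_eigenvalues` (those dropped),
#'   `proportion_explained`.
#' @export
pcoa <- function(d, k = 2) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  pos <- fit$eig[fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))]
  neg <- fit$eig[fit$eig < 0]
  n_axes <- min(length(pos), ncol(fit$points))
  if (k > n_axes) {
    warning(sprintf("k = %d exceeds the %d positive eigenvalue(s); truncating",
                    k, n_axes))
    k <- n_axes
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coords = coords,
       eigenvalues = pos,
       negative_eigenvalues = neg,
       proportion_explained = pos / sum(pos))
}

permanova_stat <- function(d2, grouping) {
  # Pseudo-F from squared dissimilarities: SS_total = sum_{i<j} d2 / n,
  # SS_within = sum over groups of within-group pair d2 / n_g.
  n <- nrow(d2)
  groups <- unique(grouping)
  a <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in groups) {
    idx <- which(grouping == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' One-factor permutational multivariate analysis of variance
#'
#' Location test on a dissimilarity matrix: the pseudo-F statistic is
#' formed from between- and within-group sums of squared dissimilarities,
#' and its null distribution from random (or, optionally, exhaustive)
#' relabelings. The permutation p-value is
#' (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' This is the one-factor test; covariate-adjusted multi-term designs are
#' deliberately out of scope and the result carries a `terms = "one-way"`
#' marker to say so.
#'
#' @param d Square dissimilarity matrix.
#' @param labels Group labels, one per sample; at least 2 groups with at
#'   least 2 samples each.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed driving the permutations.
#' @param exhaustive If `TRUE`, enumerate every distinct relabeling instead
#'   of sampling; p = #\{F >= F_obs\} / n_arrangements (the identity
#'   arrangement is included, so p > 0). Only feasible at small n.
#' @return List: `statistic` (pseudo-F), `p_value`, `n_perm`, `terms`.
#' @export
permanova_oneway <- function(d, labels, n_perm = 999, seed = 1,
                             exhaustive = FALSE) {
  labels <- as.character(labels)
  if (length(labels) != nrow(d)) stop("one label per sample required", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  d2 <- d^2
  f_obs <- permanova_stat(d2, labels)
  if (exhaustive) {
    perms <- all_label_arrangements(labels)
    f_perm <- vapply(perms, function(l) permanova_stat(d2, l), numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    f_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        permanova_stat(d2, sample(labels))
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(statistic = f_obs, p_value = p, n_perm = n_used, terms = "one-way")
}

# Every distinct assignment of the multiset of labels to positions.
all_label_arrangements <- function(labels) {
  uniq <- sort(unique(labels))
  counts <- table(factor(labels, levels = uniq))
  n <- length(labels)
  rec <- function(positions, counts_left) {
    lab <- names(counts_left)[counts_left > 0]
    if (length(positions) == 0) return(list(character(0)))
    out <- list()
    for (l in lab) {
      cl <- counts_left
      cl[l] <- cl[l] - 1
      for (rest in rec(positions[-1], cl)) {
        out[[length(out) + 1]] <- c(l, rest)
      }
    }
    out
  }
  rec(seq_len(n), counts)
}
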