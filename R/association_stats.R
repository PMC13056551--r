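#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; q-values are
#' order-preserving under permutation of the input.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Midranks are used for ties throughout. When the combined sample size is
#' at most `exact_limit` the null distribution of the rank-sum statistic is
#' enumerated exactly over all group assignments (valid under ties, where
#' the textbook exact distribution does not apply); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' The two-sided exact p-value is the null probability of a rank sum at
#' least as far from its expectation as the observed one.
#'
#' @param x,y Numeric metric vectors for the two groups (each non-empty).
#' @param exact_limit Combined-size threshold for exhaustive enumeration
#'   (default 12).
#' @return List: `statistic` (rank sum of `x` with midranks), `p_value`,
#'   `method` ("exact" or "normal").
#' @export
pairwise_rank_test <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0) stop("empty group", call. = FALSE)
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  if (m + n <= exact_limit) {
    combs <- utils::combn(m + n, m)
    w_all <- colSums(matrix(r[combs], nrow = m))
    e_w <- mean(w_all)
    p <- mean(abs(w_all - e_w) >= abs(w - e_w) - 1e-12)
    return(list(statistic = w, p_value = p, method = "exact"))
  }
  e_w <- m * (m + n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
  v_w <- m * n / 12 * ((m + n + 1) - tie_term)
  z <- (abs(w - e_w) - 0.5) / sqrt(v_w)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  list(statistic = w, p_value = p, method = "normal")
}

#' Fold change between two groups
#'
#' Ratio of arithmetic group means on the linear scale (switchable to the
#' ratio of medians).
#'
#' @param a,b Numeric vectors (numerator and denominator groups).
#' @param center `"mean"` (default) or `"median"`.
#' @return Positive fold change a/b.
#' @export
fold_change <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  f <- switch(center, mean = mean, median = stats::median)
  den <- f(b)
  if (den <= 0) stop("denominator group center must be > 0", call. = FALSE)
  num <- f(a)
  if (num <= 0) stop("numerator group center must be > 0", call. = FALSE)
  num / den
}

#' Linear mixed-effects group comparison
#'
#' Models a per-sample metric on exposure group plus clinical covariates,
#' with a random intercept for enrolment site, fitted by REML. Group
#' contrasts are reported against the reference level with Satterthwaite
#' degrees of freedom; BH adjustment is applied by the caller across
#' whatever family of metrics is run together (see [bh_adjust()]).
#'
#' With `covariates = character(0)` and `random = NULL` the fit reduces to
#' ordinary least squares on the group factor.
#'
#' @param data Tibble with the response, a `group` factor, the covariate
#'   columns and the random-effect grouping column.
#' @param response Name of the response column.
#' @param covariates Character vector of fixed-effect covariate columns
#'   (e.g. age quintile, sex, trajectory group, days from admission,
#'   steroid receipt, per-drug co-antibiotic day counts).
#' @param random Random-intercept grouping column (default `"site_id"`);
#'   `NULL` for a fixed-effects-only fit.
#' @param ref Reference group level (default `"No-Abx"`).
#' @return Tibble of group-contrast rows: `term`, `estimate`, `se`, `df`,
#'   `p`, plus per-group `n` as an attribute.
#' @export
fit_group_model <- function(data, response, covariates = character(0),
                            random = "site_id", ref = "No-Abx") {
  if (!response %in% names(data)) stop("response column missing", call. = FALSE)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    stop("covariate column(s) missing: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  data$group <- stats::relevel(factor(data$group), ref = ref)
  rhs <- paste(c("group", covariates), collapse = " + ")
  if (is.null(random)) {
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::lm(fml, data = data)
    ct <- summary(fit)$coefficients
    if (any(is.na(stats::coef(fit)))) {
      stop("singular design; collinear column(s): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
           call. = FALSE)
    }
    df_res <- fit$df.residual
    rows <- grep("^group", rownames(ct))
    res <- tibble::tibble(
      term = rownames(ct)[rows], estimate = ct[rows, 1], se = ct[rows, 2],
      df = df_res, p = ct[rows, 4]
    )
  } else {
    fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", random, ")"))
    fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
    ct <- stats::coef(summary(fit))
    rows <- grep("^group", rownames(ct))
    res <- tibble::tibble(
      term = rownames(ct)[rows], estimate = ct[rows, "Estimate"],
      se = ct[rows, "Std. Error"], df = ct[rows, "df"],
      p = ct[rows, "Pr(>|t|)"]
    )
  }
  attr(res, "n_per_group") <- table(data$group)
  attr(res, "fit") <- fit
  res
}

#' Smooth-term longitudinal exposure model
#'
#' Additive mixed model of a metric over days of azithromycin exposure:
#' cubic-regression-spline smooths (basis dimension 4) for azithromycin
#' days and each co-administered antibiotic's days, a smooth for days from
#' admission, linear terms for the clinical covariates, and a patient-level
#' random intercept. Samples are restricted to the first 10 days of
#' hospitalisation and the first 5 days of exposure before fitting, since
#' longer courses are rare and would leave the spline tail unsupported.
#'
#' Significance of the azithromycin smooth is assessed by a
#' likelihood-ratio test between maximum-likelihood refits of the nested
#' models with and without the term (REML likelihoods are not comparable
#' across fixed-effect structures, so both LRT fits use ML; the reported
#' curve comes from the REML fit).
#'
#' @param data Tibble with the response, `azithro_days`, optional co-drug
#'   day-count columns, `day_from_admission`, covariate columns and
#'   `patient_id`.
#' @param response Response column name.
#' @param co_drugs Character vector of co-antibiotic day-count columns to
#'   smooth over (columns with fewer than 3 distinct values are entered as
#'   linear terms with a warning, and the spline basis is shrunk when a
#'   column has fewer unique values than the basis dimension).
#' @param covariates Linear fixed-effect columns.
#' @param k Spline basis dimension for the antibiotic smooths (default 4).
#' @param max_day,max_exposure Inclusion caps (defaults 10 and 5).
#' @return List: `curve` (tibble of the azithromycin-day effect with
#'   pointwise 95% interval), `lrt_p`, `edf`, `fit` (REML fit), `n_used`.
#' @export
fit_exposure_trend <- function(data, response, co_drugs = character(0),
                               covariates = character(0), k = 4,
                               max_day = 10, max_exposure = 5) {
  keep <- data$day_from_admission <= max_day & data$azithro_days <= max_exposure
  data <- data[keep, , drop = FALSE]
  data$patient_id <- factor(data$patient_id)

  if (stats::var(data[[response]]) == 0) {
    # constant metric: nothing to smooth, no evidence against the null
    curve <- tibble::tibble(
      azithro_days = seq(0, max_exposure, length.out = 50),
      fit = data[[response]][1], lower = data[[response]][1],
      upper = data[[response]][1]
    )
    return(list(curve = curve, lrt_p = 1, edf = 0, fit = NULL,
                n_used = nrow(data)))
  }

  smooth_term <- function(col) {
    u <- length(unique(data[[col]]))
    if (u < 3) {
      warning(sprintf("column '%s' has %d unique value(s); entering linearly",
                      col, u))
      return(col)
    }
    kk <- min(k, u)
    if (kk < k) warning(sprintf("basis for '%s' shrunk to k = %d", col, kk))
    sprintf("s(%s, bs = 'cr', k = %d)", col, kk)
  }
  az_term <- smooth_term("azithro_days")
  co_terms <- vapply(co_drugs, smooth_term, character(1))
  u_day <- length(unique(data$day_from_admission))
  day_term <- if (u_day < 3) "day_from_admission" else
    sprintf("s(day_from_admission, bs = 'cr', k = %d)", min(10, u_day))
  re_term <- "s(patient_id, bs = 're')"
  rhs_full <- paste(c(az_term, co_terms, day_term, covariates, re_term),
                    collapse = " + ")
  rhs_null <- paste(c(co_terms, day_term, covariates, re_term),
                    collapse = " + ")
  f_full <- stats::as.formula(paste(response, "~", rhs_full))
  f_null <- stats::as.formula(paste(response, "~", rhs_null))

  fit <- mgcv::gam(f_full, data = data, method = "REML")
  fit_ml <- mgcv::gam(f_full, data = data, method = "ML")
  # Nuisance smoothing parameters are held at the full-fit values in the
  # null refit so the deviance difference isolates the exposure term;
  # re-estimating them adds noise that inflates the test.
  az_sm <- vapply(fit_ml$smooth, function(s) grepl("azithro_days", s$label),
                  logical(1))
  sp_null <- if (any(az_sm) && length(fit_ml$sp) == length(fit_ml$smooth)) {
    fit_ml$sp[!az_sm]
  } else NULL
  fit0_ml <- if (is.null(sp_null)) {
    mgcv::gam(f_null, data = data, method = "ML")
  } else {
    mgcv::gam(f_null, data = data, method = "ML", sp = sp_null)
  }
  # Likelihood ratio of the ML refits. Residual-df bookkeeping from
  # anova.gam can go negative when the patient random intercept trades
  # edf with the exposure smooth, so the chi-square reference uses the
  # exposure smooth's own effective degrees of freedom (at least 1).
  lrt_stat <- max(0, (stats::deviance(fit0_ml) - stats::deviance(fit_ml)) /
                    fit_ml$sig2)
  # Reference df = rank of the exposure smooth (basis dimension minus the
  # centring constraint). Effective-df references are anti-conservative
  # here because the penalised fit searches the full basis; the basis rank
  # bounds that search and calibrates the test (verified by the null
  # simulations in the test suite).
  az_smooths <- Filter(function(s) grepl("azithro_days", s$label),
                       fit_ml$smooth)
  lrt_df <- if (length(az_smooths) > 0) {
    max(1, sum(vapply(az_smooths, function(s) s$rank, numeric(1))))
  } else 1
  lrt_p <- stats::pchisq(lrt_stat, df = lrt_df, lower.tail = FALSE)

  grid <- tibble::tibble(azithro_days = seq(0, max_exposure, length.out = 50))
  ref_row <- data[1, , drop = FALSE]
  for (cl in c(co_drugs, "day_from_admission", covariates, "patient_id")) {
    grid[[cl]] <- ref_row[[cl]]
  }
  pr <- stats::predict(fit, newdata = grid, se.fit = TRUE,
                       exclude = "s(patient_id)", newdata.guaranteed = TRUE)
  curve <- tibble::tibble(
    azithro_days = grid$azithro_days,
    fit = as.numeric(pr$fit),
    lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
    upper = as.numeric(pr$fit + 1.96 * pr$se.fit)
  )
  edf <- sum(summary(fit)$s.table[grep("azithro_days",
                                       rownames(summary(fit)$s.table)), "edf"])
  list(curve = curve, lrt_p = lrt_p, edf = edf, fit = fit, n_used = nrow(data))
}

#' Select the most abundant taxa of a table
#'
#' @param tab Samples x taxa abundance table (RPM-kind).
#' @param n Number of taxa to keep, ranked by summed abundance (default
#'   30, the convention of the correlation analyses).
#' @return The table restricted to the top-`n` columns.
#' @export
top_taxa <- function(tab, n = 30) {
  mat <- unclass(tab)
  keep <- names(sort(colSums(mat), decreasing = TRUE))[seq_len(min(n, ncol(mat)))]
  feature_table(mat[, keep, drop = FALSE], value_kind(tab) %||% "rpm")
}

#' Spearman correlation network between taxa and resistance genes
#'
#' All pairwise Spearman correlations (midranks for ties) between taxon
#' RPM and gene DPM profiles over matched samples, with two-sided p-values
#' and BH adjustment across all defined pairs. An edge is drawn where
#' Rho > `rho_min` and q < `q_max` — a one-sided positive rule, so perfect
#' negative correlations never form edges. Pairs involving a constant
#' vector have undefined rank correlation; they are flagged and excluded
#' from the BH family.
#'
#' @param taxa_tab Samples x taxa table (typically [top_taxa()] output).
#' @param arg_tab Samples x genes table (e.g. MLS gene DPM), same samples.
#' @param rho_min Edge threshold on the coefficient (default 0.2).
#' @param q_max Edge threshold on the BH q-value (default 0.05).
#' @return List: `rho` (taxa x genes matrix), `q` (same shape, NA for
#'   undefined pairs), `edges` (tibble taxon/gene/rho/q),
#'   `undefined_pairs`.
#' @export
spearman_network <- function(taxa_tab, arg_tab, rho_min = 0.2, q_max = 0.05) {
  tx <- unclass(taxa_tab); ar <- unclass(arg_tab)
  if (!identical(rownames(tx), rownames(ar))) {
    common <- intersect(rownames(tx), rownames(ar))
    if (length(common) < 3) stop("fewer than 3 matched samples", call. = FALSE)
    tx <- tx[common, , drop = FALSE]; ar <- ar[common, , drop = FALSE]
  }
  const_tx <- apply(tx, 2, function(v) length(unique(v)) == 1)
  const_ar <- apply(ar, 2, function(v) length(unique(v)) == 1)
  rho <- matrix(NA_real_, ncol(tx), ncol(ar),
                dimnames = list(colnames(tx), colnames(ar)))
  pmat <- rho
  for (i in seq_len(ncol(tx))) {
    for (j in seq_len(ncol(ar))) {
      if (const_tx[i] || const_ar[j]) next
      ct <- suppressWarnings(
        stats::cor.test(tx[, i], ar[, j], method = "spearman", exact = FALSE)
      )
      rho[i, j] <- unname(ct$estimate)
      pmat[i, j] <- ct$p.value
    }
  }
  q <- pmat
  defined <- !is.na(pmat)
  q[defined] <- bh_adjust(pmat[defined])
  edge_idx <- which(defined & rho > rho_min & q < q_max, arr.ind = TRUE)
  edges <- tibble::tibble(
    taxon = rownames(rho)[edge_idx[, 1]],
    gene = colnames(rho)[edge_idx[, 2]],
    rho = rho[edge_idx],
    q = q[edge_idx]
  )
  undefined <- expand.grid(taxon = colnames(tx)[const_tx],
                           gene = colnames(ar), stringsAsFactors = FALSE)
  undefined2 <- expand.grid(taxon = colnames(tx),
                            gene = colnames(ar)[const_ar], stringsAsFactors = FALSE)
  list(rho = rho, q = q, edges = edges,
       undefined_pairs = unique(rbind(undefined, undefined2)))
}
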