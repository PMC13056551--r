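test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- p[o] * m / seq_len(m)
    # enforce monotonicity from the largest rank down
    q_sorted <- rev(cummin(rev(q_sorted)))
    q <- numeric(m)
    q[o] <- pmin(1, q_sorted)
    q
  }
  withr::with_seed(12, {
    for (i in 1:20) {
      p <- runif(sample(2:40, 1))
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
      expect_true(all(bh_adjust(p) >= p - 1e-15))
      perm <- sample(length(p))
      expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
    }
  })
})

test_that("rank-sum test: exact enumeration at small n, including ties", {
  expect_equal(pairwise_rank_test(5, 5)$p_value, 1)
  expect_error(pairwise_rank_test(numeric(0), 1), "empty")

  r <- pairwise_rank_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)  # 2 / choose(6, 3)

  # independent enumeration oracle (with midranks, two-sided deviation)
  exact_oracle <- function(x, y) {
    m <- length(x)
    r <- rank(c(x, y))
    subsets <- utils::combn(length(r), m)
    w_all <- apply(subsets, 2, function(ii) sum(r[ii]))
    w_obs <- sum(r[seq_len(m)])
    mean(abs(w_all - mean(w_all)) >= abs(w_obs - mean(w_all)) - 1e-12)
  }
  withr::with_seed(3, {
    for (i in 1:20) {
      m <- sample(2:6, 1); n <- sample(2:6, 1)
      x <- sample(1:8, m, TRUE); y <- sample(1:8, n, TRUE)  # ties likely
      expect_equal(pairwise_rank_test(x, y)$p_value, exact_oracle(x, y),
                   tolerance = 1e-12)
    }
  })

  # tie-free exact mode agrees with the classical exact distribution
  withr::with_seed(4, {
    for (i in 1:10) {
      x <- runif(5); y <- runif(6)
      ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
      expect_equal(pairwise_rank_test(x, y)$p_value, ref, tolerance = 1e-10)
    }
  })
})

test_that("rank-sum normal approximation tracks the standard implementation", {
  withr::with_seed(9, {
    x <- rnorm(30); y <- rnorm(25, 0.5)
    got <- pairwise_rank_test(x, y)
    expect_equal(got$method, "normal")
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_equal(got$p_value, ref, tolerance = 1e-8)
    # with ties
    xt <- sample(1:6, 30, TRUE); yt <- sample(2:8, 25, TRUE)
    reft <- suppressWarnings(
      stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE))$p.value
    expect_equal(pairwise_rank_test(xt, yt)$p_value, reft, tolerance = 1e-8)
  })
})

test_that("fold change is the ratio of group centers", {
  expect_equal(fold_change(c(3, 5), c(3, 5)), 1)
  expect_equal(fold_change(c(2, 2), c(1, 1)), 2)
  expect_error(fold_change(c(1, 2), c(0, 0)), "denominator")
  withr::with_seed(2, {
    a <- runif(10, 1, 5); b <- runif(8, 1, 5)
    expect_equal(fold_change(a, b), mean(a) / mean(b))
    expect_equal(fold_change(a, b, center = "median"),
                 median(a) / median(b))
  })
})

test_that("group model reduces to OLS difference of means without covariates", {
  withr::with_seed(7, {
    dat <- tibble::tibble(
      group = rep(c("Azithro", "No-Abx"), each = 30),
      y = rnorm(60) + rep(c(1.3, 0), each = 30)
    )
  })
  res <- fit_group_model(dat, "y", covariates = character(0), random = NULL)
  expect_equal(res$estimate,
               mean(dat$y[dat$group == "Azithro"]) -
                 mean(dat$y[dat$group == "No-Abx"]),
               tolerance = 1e-10)
})

test_that("group model recovers a known effect with a site random intercept", {
  sim_group_data <- function(delta, n = 200, n_site = 10, seed = 1) {
    withr::with_seed(seed, {
      site <- sample(sprintf("site%02d", 1:n_site), n, TRUE)
      site_eff <- setNames(rnorm(n_site, sd = 0.5), sprintf("site%02d", 1:n_site))
      group <- sample(c("Azithro", "No-Abx"), n, TRUE)
      tibble::tibble(
        group = group, site_id = site,
        y = delta * (group == "Azithro") + site_eff[site] + rnorm(n)
      )
    })
  }
  est <- vapply(1:5, function(s) {
    fit_group_model(sim_group_data(1.0, seed = s), "y")$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.0), 0.2)
  # missing covariate column is a clear error
  expect_error(
    fit_group_model(sim_group_data(1, seed = 1), "y", covariates = "age"),
    "covariate"
  )
})

test_that("exposure trend model detects a linear effect and stays flat under none", {
  sim_trend_data <- function(beta, n = 300, seed = 1) {
    withr::with_seed(seed, {
      pid <- sample(sprintf("P%02d", 1:60), n, TRUE)
      p_eff <- setNames(rnorm(60, sd = 0.5), sprintf("P%02d", 1:60))
      az <- sample(0:5, n, TRUE)
      tibble::tibble(
        patient_id = pid, azithro_days = az,
        day_from_admission = sample(0:10, n, TRUE),
        y = beta * az + p_eff[pid] + rnorm(n)
      )
    })
  }
  rises <- vapply(1:3, function(s) {
    fit <- fit_exposure_trend(sim_trend_data(0.5, seed = s), "y")
    diff(range(fit$curve$fit[c(1, nrow(fit$curve))]))
  }, numeric(1))
  expect_true(all(abs(rises - 2.5) / 2.5 < 0.3))

  flat <- fit_exposure_trend(
    dplyr::mutate(sim_trend_data(0, seed = 9), y = 1.0), "y")
  expect_lt(diff(range(flat$curve$fit)), 1e-6)
  expect_gt(flat$lrt_p, 0.5)
})

test_that("exposure trend restricts samples and shrinks degenerate bases", {
  withr::with_seed(5, {
    dat <- tibble::tibble(
      patient_id = sample(sprintf("P%02d", 1:30), 200, TRUE),
      azithro_days = sample(0:8, 200, TRUE),
      day_from_admission = sample(0:20, 200, TRUE),
      co = sample(0:1, 200, TRUE),
      y = rnorm(200)
    )
  })
  fit <- suppressWarnings(fit_exposure_trend(dat, "y", co_drugs = "co"))
  expect_equal(fit$n_used,
               sum(dat$day_from_admission <= 10 & dat$azithro_days <= 5))
  expect_warning(fit_exposure_trend(dat, "y", co_drugs = "co"), "linear")
})

test_that("spearman network applies the one-sided positive edge rule", {
  withr::with_seed(31, {
    n <- 40
    base <- runif(n)
    tx <- cbind(up = base + rnorm(n, sd = 0.01),
                down = -base + rnorm(n, sd = 0.01),
                noise = runif(n),
                flat = rep(1, n))
    ar <- cbind(g1 = base^3)  # strictly monotone transform of base
    rownames(tx) <- rownames(ar) <- sprintf("S%02d", 1:n)
  })
  net <- spearman_network(tx, ar)
  expect_equal(unname(net$rho["up", "g1"]), 1, tolerance = 0.02)
  expect_lt(net$rho["down", "g1"], -0.9)
  expect_true(all(net$edges$taxon != "down"))   # negative rho never an edge
  expect_true("up" %in% net$edges$taxon)
  expect_true(is.na(net$rho["flat", "g1"]))     # constant vector undefined
  expect_true(nrow(net$undefined_pairs) >= 1)
})

test_that("spearman grid equals a rank-then-Pearson oracle", {
  withr::with_seed(44, {
    tx <- matrix(rnorm(25 * 4), 25, 4,
                 dimnames = list(sprintf("S%02d", 1:25), paste0("t", 1:4)))
    ar <- matrix(rnorm(25 * 3), 25, 3,
                 dimnames = list(sprintf("S%02d", 1:25), paste0("g", 1:3)))
  })
  net <- spearman_network(tx, ar)
  for (i in 1:4) for (j in 1:3) {
    oracle <- stats::cor(rank(tx[, i]), rank(ar[, j]))
    expect_equal(unname(net$rho[i, j]), oracle, tolerance = 1e-10)
  }
  # invariance under strictly monotone transforms
  net2 <- spearman_network(exp(tx), ar)
  expect_equal(net2$rho, net$rho, tolerance = 1e-10)
})

test_that("top_taxa ranks by summed abundance", {
  mat <- matrix(c(10, 10, 1, 1, 5, 5), 2,
                dimnames = list(c("S1", "S2"), c("big", "small", "mid")))
  out <- top_taxa(mat, 2)
  expect_equal(colnames(out), c("big", "mid"))
})
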