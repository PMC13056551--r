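make_null_fixture <- function(theta = 2, n_controls = 26, n_features = 200,
                              seed = 1, batches = c("1", "2", "3A", "3B")) {
  withr::with_seed(seed, {
    batch <- rep(batches, length.out = n_controls)
    mu <- matrix(rlnorm(length(batches) * n_features, log(15), 1),
                 nrow = length(batches),
                 dimnames = list(batches, sprintf("f%03d", 1:n_features)))
    counts <- t(vapply(seq_len(n_controls), function(i) {
      rnbinom(n_features, size = theta, mu = mu[batch[i], ])
    }, numeric(n_features)))
    rownames(counts) <- sprintf("NC%02d", 1:n_controls)
    colnames(counts) <- colnames(mu)
    list(counts = counts, batch = batch, mu = mu, theta = theta)
  })
}

test_that("null means are per batch:feature control sample means", {
  counts <- matrix(c(2, 4, 7, 1), nrow = 2,
                   dimnames = list(c("c1", "c2"), c("fA", "fB")))
  null <- fit_null(counts, c("1", "1"))
  expect_equal(unname(null$mu["1", "fA"]), 3)
  expect_equal(unname(null$mu["1", "fB"]), 4)
})

test_that("dispersion is recovered from simulated controls and matches oracles", {
  # fixing cell means at their sample means inflates theta slightly at 6-7
  # controls per batch, so recovery is judged on the average over seeds
  thetas <- vapply(1:20, function(s) {
    fx <- make_null_fixture(theta = 2, seed = s)
    fit_null(fx$counts, fx$batch)$theta
  }, numeric(1))
  expect_lt(abs(mean(thetas) - 2) / 2, 0.25)

  fx <- make_null_fixture(theta = 2, seed = 99)
  null <- fit_null(fx$counts, fx$batch)
  mu_obs <- null$mu[cbind(match(fx$batch, rownames(null$mu)),
                          rep(seq_len(ncol(fx$counts)), each = nrow(fx$counts)))]
  x <- as.vector(fx$counts)
  keep <- mu_obs > 0

  # oracle 1: grid search of the same profile likelihood
  grid <- exp(seq(log(0.1), log(50), length.out = 4000))
  ll <- vapply(grid, function(th) {
    sum(dnbinom(x[keep], size = th, mu = mu_obs[keep], log = TRUE))
  }, numeric(1))
  expect_equal(null$theta, grid[which.max(ll)], tolerance = 2e-3)

  # oracle 2: the standard dispersion ML fit with the same fixed means
  mt <- MASS::theta.ml(x[keep], mu_obs[keep], limit = 100)
  expect_equal(null$theta, as.numeric(mt), tolerance = 1e-3)
})

test_that("zero-variance counts drive theta to the Poisson-limit boundary", {
  counts <- matrix(5, nrow = 4, ncol = 1,
                   dimnames = list(paste0("c", 1:4), "fA"))
  null <- fit_null(counts, rep("1", 4))
  expect_true(null$theta_boundary)
  expect_equal(null$theta, null$theta_bounds[2])
})

test_that("all-zero controls are rejected", {
  counts <- matrix(0, 3, 2, dimnames = list(paste0("c", 1:3), c("a", "b")))
  expect_error(fit_null(counts, rep("1", 3)), "no contamination signal")
})

test_that("tail_pvalue matches brute-force pmf summation and handles edge cases", {
  expect_equal(tail_pvalue(0, 5, 2), 1)
  expect_equal(tail_pvalue(0, 0, 2), 1)
  expect_equal(tail_pvalue(3, 0, 2), 0)
  expect_error(tail_pvalue(2.5, 1, 1), "integer")

  brute <- function(x, mu, theta) {
    if (x == 0) return(1)
    1 - sum(dnbinom(0:(x - 1), size = theta, mu = mu))
  }
  expect_equal(tail_pvalue(10, 5, 2), brute(10, 5, 2), tolerance = 1e-12)
  withr::with_seed(4, {
    for (i in 1:200) {
      x <- sample(0:40, 1); mu <- runif(1, 0.1, 30); th <- runif(1, 0.2, 10)
      expect_lt(abs(tail_pvalue(x, mu, th) - brute(x, mu, th)), 1e-10)
    }
  })
})

test_that("tail_pvalue is monotone in x and reaches the Poisson limit", {
  p <- tail_pvalue(0:30, 6, 1.5)
  expect_true(all(diff(p) <= 1e-15))
  x <- 0:40
  expect_lt(max(abs(tail_pvalue(x, 7, 1e6) -
                      ppois(x - 1, 7, lower.tail = FALSE))), 1e-6)
})

test_that("features unseen in controls are retained and flagged, outside the BH family", {
  fx <- make_null_fixture(seed = 12, n_features = 20)
  null <- fit_null(fx$counts, fx$batch)
  mat <- matrix(rpois(3 * 21, 10), nrow = 3,
                dimnames = list(paste0("S", 1:3),
                                c(colnames(fx$counts)[1:20], "novel")))
  mat[1, "novel"] <- 7
  res <- apply_decontam(feature_table(mat, "reads"), rep("1", 3), null)
  nov <- res$decisions[res$decisions$feature == "novel", ]
  expect_true(all(nov$retained))
  expect_true(all(nov$unseen_in_controls))
  expect_true(all(is.na(nov$q)))
})

test_that("decontamination is deterministic and idempotent", {
  fx <- make_null_fixture(seed = 21, n_features = 50)
  null <- fit_null(fx$counts, fx$batch)
  withr::with_seed(8, {
    mat <- matrix(rnbinom(10 * 50, size = 2,
                          mu = rep(fx$mu["1", ], each = 10)), nrow = 10)
    dimnames(mat) <- list(sprintf("S%02d", 1:10), colnames(fx$counts))
  })
  tab <- feature_table(mat, "reads")
  r1 <- apply_decontam(tab, rep("1", 10), null)
  r2 <- apply_decontam(tab, rep("1", 10), null)
  expect_identical(r1$decisions, r2$decisions)
  r3 <- apply_decontam(r1$table, rep("1", 10), null)
  expect_equal(unclass(r3$table), unclass(r1$table), ignore_attr = TRUE)
})

test_that("unknown batches are reported by name", {
  fx <- make_null_fixture(seed = 3, n_features = 5)
  null <- fit_null(fx$counts, fx$batch)
  mat <- matrix(1, 1, 5, dimnames = list("S1", colnames(fx$counts)))
  expect_error(apply_decontam(feature_table(mat, "reads"), "batchX", null),
               "batchX")
})

test_that("null p-values satisfy the exceedance bound P(p <= t) <= t", {
  fx <- make_null_fixture(theta = 2, seed = 31)
  null <- list(mu = fx$mu, theta = fx$theta)  # use the true null: calibration check
  class(null) <- "decontam_null"
  withr::with_seed(77, {
    n_samp <- 40
    batch <- rep(rownames(fx$mu), length.out = n_samp)
    mat <- t(vapply(seq_len(n_samp), function(i) {
      rnbinom(ncol(fx$mu), size = fx$theta, mu = fx$mu[batch[i], ])
    }, numeric(ncol(fx$mu))))
    dimnames(mat) <- list(sprintf("S%02d", 1:n_samp), colnames(fx$mu))
  })
  res <- apply_decontam(feature_table(mat, "reads"), batch, null)
  p <- res$decisions$p[!res$decisions$unseen_in_controls]
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    # slack = 3 binomial MC standard errors at each grid point
    expect_lte(mean(p <= t), t + 3 * sqrt(t * (1 - t) / length(p)))
  }
})
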