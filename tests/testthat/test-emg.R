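# EMG density, distribution function, and maximum-likelihood fitting.

test_that("EMG density matches an independent reference implementation", {
  # reference values from scipy.stats.exponnorm (K = 1/(sigma*lam))
  expect_equal(demg(1.0, 1, 0.2, 2, log = TRUE), -0.2922868686296314,
               tolerance = 1e-10)
  expect_equal(demg(3.0, 1, 0.2, 2, log = TRUE), -3.2268528194400554,
               tolerance = 1e-10)
  # narrow normal + fast tail far from the mode: must not overflow/underflow
  expect_equal(demg(0.2, 1, 0.05, 50, log = TRUE), -127.9275870591185,
               tolerance = 1e-9)
})

test_that("EMG density integrates to 1 and approaches the normal limit", {
  for (p in list(c(1, 0.2, 2), c(0.5, 0.1, 10), c(2, 0.4, 0.25))) {
    expect_equal(
      stats::integrate(function(x) demg(x, p[1], p[2], p[3]), -Inf, Inf)$value,
      1, tolerance = 1e-6)
  }
  # lam large: exponential mass vanishes, density tends to normal(mu, sigma^2)
  expect_equal(demg(1.1, 1, 0.2, 1e5), stats::dnorm(1.1, 1, 0.2),
               tolerance = 1e-3)
})

test_that("EMG survival function agrees with numeric quadrature", {
  ref <- function(q) stats::integrate(function(x) demg(x, 1, 0.2, 2),
                                      q, Inf, rel.tol = 1e-12)$value
  for (q in c(0.5, 1, 2, 5, 10)) {
    expect_equal(pemg(q, 1, 0.2, 2, lower.tail = FALSE), ref(q),
                 tolerance = 1e-8)
  }
  expect_equal(pemg(2, 1, 0.2, 2, lower.tail = FALSE), 0.14660693908135544,
               tolerance = 1e-10)  # scipy sf
})

test_that("emg_loglik rejects non-finite data and sums log densities", {
  x <- c(0.8, 1.1, 1.5)
  expect_equal(emg_loglik(list(mu = 1, sigma = 0.2, lam = 2), x),
               sum(demg(x, 1, 0.2, 2, log = TRUE)))
  expect_error(emg_loglik(list(mu = 1, sigma = 0.2, lam = 2), c(1, NA)),
               "non-finite")
})

test_that("MLE recovers parameters and is deterministic on a fixed sample", {
  set.seed(71)
  x <- remg(10000, 1.0, 0.2, 2.0)
  fit <- fit_emg(x)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$mu - 1.0), 0.05)
  expect_lt(abs(fit$sigma - 0.2), 0.05)
  expect_lt(abs(fit$lam - 2.0) / 2.0, 0.15)
  refit <- fit_emg(x)
  expect_identical(fit[c("mu", "sigma", "lam")],
                   refit[c("mu", "sigma", "lam")])
})

test_that("a pure-normal sample yields mu near the sample mean and a fast tail", {
  set.seed(72)
  x <- rnorm(5000, 1, 0.15)
  fit <- fit_emg(x)
  expect_equal(fit$status, "ok")
  # EMG mean identity: mu + 1/lam must track the sample mean, with the
  # exponential mean well below the normal width
  expect_lt(abs(fit$mu + 1 / fit$lam - mean(x)), 0.02)
  expect_lt(1 / fit$lam, fit$sigma)
  expect_gt(fit$lam, 10)
})

test_that("fitted likelihood is at least the truth's on most replicates", {
  # MLE self-consistency: optimum can't fall below the generating params
  # (up to optimizer tolerance)
  wins <- 0L
  for (r in 1:40) {
    set.seed(100 + r)
    x <- remg(800, 1, 0.2, 2)
    fit <- fit_emg(x)
    ll_true <- emg_loglik(list(mu = 1, sigma = 0.2, lam = 2), x)
    if (fit$loglik >= ll_true - 1e-4) wins <- wins + 1L
  }
  expect_gte(wins, 38L)
})

test_that("undersized samples are refused", {
  expect_equal(fit_emg(rnorm(99))$status, "insufficient_n")
})

test_that("outlier removal obeys the expected-count rule and is monotone", {
  fit <- list(mu = 1, sigma = 0.2, lam = 2)
  set.seed(73)
  x <- remg(1000, 1, 0.2, 2)
  # a point 50 sigma beyond mu is removed, bulk points are not
  x_ext <- c(x, 1 + 50 * 0.2 * 10)
  res <- remove_outliers(x_ext, fit)
  expect_false(max(x_ext) %in% res$values)
  # points near mu have survival ~ 0.5: p*n >> threshold, nothing removed
  bulk <- rep(1, 200)
  expect_equal(remove_outliers(bulk, fit)$removed, 0)
  # monotonicity: lowering the threshold never removes more points
  r_hi <- remove_outliers(x_ext, fit, threshold = 0.01)
  r_lo <- remove_outliers(x_ext, fit, threshold = 0.0001)
  expect_lte(r_lo$removed, r_hi$removed)
})
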