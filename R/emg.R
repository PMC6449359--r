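## Exponentially modified Gaussian (EMG): X = N(mu, sigma^2) + Exp(rate = lam).
## The normal component models the typical decoding time of a codon; the
## exponential tail absorbs pauses, traffic jams and other non-typical events.

# log erfcx(u) for u >= 0: pracma::erfcx up to u = 25, then the standard
# asymptotic expansion erfcx(u) ~ 1/(u sqrt(pi)) (1 - 1/(2u^2) + 3/(4u^4)).
log_erfcx_nonneg <- function(u) {
  out <- numeric(length(u))
  small <- u <= 25
  if (any(small)) out[small] <- log(pracma::erfcx(u[small]))
  if (any(!small)) {
    ub <- u[!small]
    out[!small] <- -log(ub) - 0.5 * log(pi) +
      log1p(-1 / (2 * ub^2) + 3 / (4 * ub^4))
  }
  out
}

#' Exponentially modified Gaussian density
#'
#' Density of `X = N(mu, sigma^2) + Exp(rate = lam)`, evaluated in a
#' numerically stable log form (via the scaled complementary error function)
#' so that narrow normal components with large exponential rates do not
#' overflow.
#'
#' @param x Numeric vector of quantiles.
#' @param mu Mean of the normal component (> 0 for accepted decoding fits).
#' @param sigma Standard deviation of the normal component (> 0).
#' @param lam Rate of the exponential component (> 0); the tail has mean
#'   `1/lam`.
#' @param log If `TRUE`, return log density.
#' @return Numeric vector of (log) densities.
#' @export
demg <- function(x, mu, sigma, lam, log = FALSE) {
  stopifnot(sigma > 0, lam > 0)
  u <- (mu + lam * sigma^2 - x) / (sigma * sqrt(2))
  lf <- numeric(length(x))
  pos <- u >= 0
  if (any(pos)) {
    lf[pos] <- base::log(lam / 2) + log_erfcx_nonneg(u[pos]) -
      (x[pos] - mu)^2 / (2 * sigma^2)
  }
  if (any(!pos)) {
    # right tail: exponential decay times erfc(u) ~ 2; no u^2 cancellation
    lf[!pos] <- base::log(lam / 2) + lam * (mu - x[!pos]) +
      lam^2 * sigma^2 / 2 + base::log(2) +
      stats::pnorm(u[!pos] * sqrt(2), lower.tail = FALSE, log.p = TRUE)
  }
  if (log) lf else exp(lf)
}

#' Exponentially modified Gaussian distribution function
#'
#' @inheritParams demg
#' @param q Numeric vector of quantiles.
#' @param lower.tail If `FALSE`, return the survival probability
#'   `P(X >= q)`, the quantity used by the outlier-removal rule.
#' @return Numeric vector of probabilities.
#' @export
pemg <- function(q, mu, sigma, lam, lower.tail = TRUE) {
  stopifnot(sigma > 0, lam > 0)
  v <- (q - mu) / sigma
  # S(q) = Q(v) + exp(lam*(mu - q) + lam^2 sigma^2 / 2) * Phi(v - lam*sigma),
  # second term computed in log space to survive far tails.
  lt2 <- lam * (mu - q) + lam^2 * sigma^2 / 2 +
    stats::pnorm(v - lam * sigma, log.p = TRUE)
  s <- stats::pnorm(v, lower.tail = FALSE) + exp(lt2)
  s <- pmin(pmax(s, 0), 1)
  if (lower.tail) 1 - s else s
}

#' Draw from an exponentially modified Gaussian
#'
#' @inheritParams demg
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
remg <- function(n, mu, sigma, lam) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = lam)
}

#' EMG log-likelihood of a sample
#'
#' @param params Numeric vector or list with elements `mu`, `sigma`, `lam`.
#' @param values Numeric vector of observations (finite).
#' @return Sum of log densities.
#' @export
emg_loglik <- function(params, values) {
  if (!all(is.finite(values))) stop("non-finite value in input")
  params <- as.list(params)
  sum(demg(values, params$mu, params$sigma, params$lam, log = TRUE))
}

# Method-of-moments starting point (standard EMG moment inversion, guarded
# against non-positive skewness where the pure-normal limit is returned).
emg_moments_init <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  g1 <- mean((x - m)^3) / s^3
  if (is.finite(g1) && g1 > 0.005) {
    k <- (g1 / 2)^(1 / 3)
    mu <- m - s * k
    sig2 <- s^2 * max(1 - k^2, 0.05)
    lam <- 1 / (s * k)
    list(mu = mu, sigma = sqrt(sig2), lam = lam)
  } else {
    list(mu = m, sigma = s, lam = 20 / max(s, 1e-8))
  }
}

#' Fit an EMG distribution by maximum likelihood
#'
#' Multi-start local optimisation (Nelder-Mead on `(mu, log sigma, log lam)`)
#' from a method-of-moments starting point plus deterministic perturbations
#' of it, so repeated fits of the same sample give identical parameters.
#' The EMG likelihood can be multimodal when the exponential component is
#' heavy, hence the multiple starts.
#'
#' @param values Numeric vector of observations (for codon NFC samples the
#'   admission rule requires at least 100 values).
#' @param n_starts Number of optimisation starts (>= 1).
#' @param min_n Minimum sample size admitted to fitting.
#' @return List with `mu`, `sigma`, `lam`, `loglik`, `status`
#'   (`"ok"`, `"insufficient_n"` or `"fit_failed"`), and `n`.
#' @export
fit_emg <- function(values, n_starts = 5, min_n = 100) {
  n <- length(values)
  if (n < min_n) {
    return(list(mu = NA_real_, sigma = NA_real_, lam = NA_real_,
                loglik = NA_real_, status = "insufficient_n", n = n))
  }
  init <- emg_moments_init(values)
  # deterministic perturbation grid around the moment start
  starts <- list(
    c(init$mu, log(init$sigma), log(init$lam)),
    c(init$mu, log(init$sigma), log(init$lam * 3)),
    c(init$mu, log(init$sigma), log(init$lam / 3)),
    c(init$mu * 0.9, log(init$sigma * 1.5), log(init$lam)),
    c(mean(values) * 0.8, log(stats::sd(values) * 0.8),
      log(5 / max(stats::sd(values), 1e-8))),
    c(init$mu * 1.05, log(init$sigma * 0.6), log(init$lam * 10))
  )
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  nll <- function(p) {
    mu <- p[1]; sigma <- exp(p[2]); lam <- exp(p[3])
    if (!is.finite(mu) || sigma <= 0 || lam <= 0) return(1e12)
    v <- -sum(demg(values, mu, sigma, lam, log = TRUE))
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(mu = NA_real_, sigma = NA_real_, lam = NA_real_,
                loglik = NA_real_, status = "fit_failed", n = n))
  }
  list(mu = best$par[1], sigma = exp(best$par[2]), lam = exp(best$par[3]),
       loglik = -best$value, status = "ok", n = n)
}

#' Remove outliers from a codon NFC sample under a fitted EMG
#'
#' A point with normalized footprint count `NFC_i` is removed when
#' `p_i * n_i < threshold`, where `p_i` is the fitted probability of seeing a
#' value at least as large and `n_i` the sample size: values this extreme
#' are expected to occur less than `threshold` times in the whole sample.
#'
#' @param values Numeric sample.
#' @param fit Converged EMG fit (list with `mu`, `sigma`, `lam`).
#' @param threshold Removal threshold on the expected count (default 0.001).
#' @return List with `values` (retained points) and `removed` (count).
#' @export
remove_outliers <- function(values, fit, threshold = 0.001) {
  n <- length(values)
  p <- pemg(values, fit$mu, fit$sigma, fit$lam, lower.tail = FALSE)
  keep <- p * n >= threshold
  list(values = values[keep], removed = sum(!keep))
}
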