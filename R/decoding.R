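## Stage 2-3 of the MTDR procedure: per-codon EMG fits with one outlier
## removal pass and a refit, typical decoding rates TDR = 1/mu, per-gene
## MTDR (geometric mean over codon positions) and per-time-point z-scores.

#' Estimate the codon TDR table from per-codon NFC samples
#'
#' For each codon and time point: fit the EMG by maximum likelihood, remove
#' outliers under the fitted distribution (`p_i * n_i < threshold`), refit
#' once, and set TDR to `1/mu` of the final fit.  Ranks (1 = slowest) are
#' computed per time point over fitted codons, ties broken by average rank.
#'
#' @param samples Per-time-point codon NFC samples from
#'   [collect_codon_nfc()].
#' @param outlier_threshold Removal threshold (default 0.001).
#' @param n_starts Optimisation starts per fit.
#' @param min_n Minimum admitted sample size (default 100).
#' @return List with `tdr` (61 x T matrix, NA where unfitted), `ranks`
#'   (61 x T, NA where unfitted), `status` (61 x T character), and
#'   `diagnostics` (data.frame of mu, sigma, lam, n, removed, loglik per
#'   fitted cell).
#' @export
estimate_tdr_table <- function(samples, outlier_threshold = 0.001,
                               n_starts = 5, min_n = 100) {
  codons <- sense_codons()
  tps <- names(samples)
  tdr <- matrix(NA_real_, 61, length(tps), dimnames = list(codons, tps))
  status <- matrix("insufficient_n", 61, length(tps),
                   dimnames = list(codons, tps))
  diag_rows <- list()
  for (tp in tps) {
    vals <- samples[[tp]]$values
    for (codon in names(vals)) {
      x <- vals[[codon]]
      fit1 <- fit_emg(x, n_starts = n_starts, min_n = min_n)
      if (fit1$status != "ok") {
        status[codon, tp] <- fit1$status
        next
      }
      pruned <- remove_outliers(x, fit1, outlier_threshold)
      fit2 <- fit_emg(pruned$values, n_starts = n_starts, min_n = min_n)
      if (fit2$status != "ok" || fit2$mu <= 0) {
        status[codon, tp] <- "fit_failed"
        next
      }
      tdr[codon, tp] <- 1 / fit2$mu
      status[codon, tp] <- "ok"
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        codon = codon, time_point = tp, mu = fit2$mu, sigma = fit2$sigma,
        lam = fit2$lam, n = length(x), removed = pruned$removed,
        loglik = fit2$loglik, stringsAsFactors = FALSE)
    }
  }
  ranks <- apply(tdr, 2, function(col) {
    r <- rep(NA_real_, length(col))
    ok <- !is.na(col)
    r[ok] <- rank(col[ok], ties.method = "average")
    r
  })
  dimnames(ranks) <- dimnames(tdr)
  list(tdr = tdr, ranks = ranks, status = status,
       diagnostics = do.call(rbind, diag_rows))
}

#' Per-gene MTDR: geometric mean of codon TDRs
#'
#' Every codon position contributes (repeated codons weighted by
#' occurrence).  Codons without a fitted TDR at the time point are either
#' imputed with the time point's mean log-TDR (default, the gene is
#' flagged) or cause the gene to be dropped.
#'
#' @param codons Character vector: the gene's in-frame codons.
#' @param tdr_column Named numeric vector of TDRs at one time point
#'   (NA = unfitted).
#' @param unfitted `"impute"` (default) or `"drop"`.
#' @return List with `mtdr` (NA when dropped) and `imputed` (count of
#'   imputed positions).
#' @export
gene_mtdr <- function(codons, tdr_column, unfitted = c("impute", "drop")) {
  unfitted <- match.arg(unfitted)
  v <- tdr_column[codons]
  if (any(!is.na(v) & v <= 0)) stop("non-positive TDR encountered")
  n_missing <- sum(is.na(v))
  if (n_missing > 0) {
    if (unfitted == "drop" || all(is.na(v))) {
      return(list(mtdr = NA_real_, imputed = n_missing))
    }
    v[is.na(v)] <- exp(mean(log(tdr_column[!is.na(tdr_column)])))
  }
  list(mtdr = exp(mean(log(v))), imputed = n_missing)
}

#' Gene x time-point MTDR matrix
#'
#' @param genome Named list of codon vectors.
#' @param tdr 61 x T TDR matrix from [estimate_tdr_table()].
#' @param unfitted Passed to [gene_mtdr()].
#' @return List with `mtdr` (gene x T matrix) and `imputed` (gene x T count
#'   of imputed codon positions).
#' @export
mtdr_matrix <- function(genome, tdr, unfitted = "impute") {
  tps <- colnames(tdr)
  m <- matrix(NA_real_, length(genome), length(tps),
              dimnames = list(names(genome), tps))
  imp <- m
  for (tp in tps) {
    col <- tdr[, tp]
    for (g in names(genome)) {
      r <- gene_mtdr(genome[[g]], col, unfitted)
      m[g, tp] <- r$mtdr
      imp[g, tp] <- r$imputed
    }
  }
  list(mtdr = m, imputed = imp)
}

#' Standardize an MTDR matrix to per-time-point z-scores
#'
#' Each column is centred on its mean and divided by its sample (n-1)
#' standard deviation, so z-scores measure a gene's distance from the
#' time-point average and are comparable across time points with different
#' coverage.  Missing cells propagate.
#'
#' @param m gene x T MTDR matrix.
#' @return gene x T z-score matrix.
#' @export
standardize_mtdr <- function(m) {
  z <- apply(m, 2, function(col) {
    ok <- !is.na(col)
    if (sum(ok) < 2) stop("need >= 2 finite MTDR values per time point")
    s <- stats::sd(col[ok])
    if (s == 0) stop("degenerate time point: zero MTDR standard deviation")
    (col - mean(col[ok])) / s
  })
  dimnames(z) <- dimnames(m)
  z
}

#' Median-based decoding rates (robustness variant)
#'
#' Rate = 1 / median(NFC) per admitted codon sample; a distribution-free
#' counterpart to the EMG-based TDR used to check that conclusions do not
#' hinge on the parametric fit.
#'
#' @param samples Per-time-point codon NFC samples from
#'   [collect_codon_nfc()].
#' @return 61 x T matrix (NA where not admitted; zero medians flagged NA
#'   with a warning).
#' @export
median_based_rates <- function(samples) {
  codons <- sense_codons()
  tps <- names(samples)
  m <- matrix(NA_real_, 61, length(tps), dimnames = list(codons, tps))
  for (tp in tps) {
    vals <- samples[[tp]]$values
    for (codon in names(vals)) {
      md <- stats::median(vals[[codon]])
      if (md <= 0) {
        warning("zero median NFC for ", codon, " @ ", tp)
        next
      }
      m[codon, tp] <- 1 / md
    }
  }
  m
}
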