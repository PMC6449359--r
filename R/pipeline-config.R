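## Single source of truth for the pipeline's constants and thresholds.  The
## defaults are the study's stated values: 20-codon end trimming, inclusive
## 40% coverage threshold, 100-occurrence codon admission, 0.001 outlier
## rule, 10-codon ribosome footprint, 200,000 ribosomes and 60,000 mRNAs.

#' Validated pipeline configuration
#'
#' @param n_trim Codons trimmed from each profile end.
#' @param min_coverage Inclusive coverage threshold between 0 and 1.
#' @param min_n Minimum codon occurrences admitted to fitting.
#' @param outlier_threshold Outlier-removal threshold on `p * n`.
#' @param footprint Ribosome footprint in codons.
#' @param total_ribosomes Whole-cell ribosome pool.
#' @param total_mrnas Whole-cell mRNA count.
#' @param include_zeros Include zero-count positions in NFC normalization.
#' @param seed Master seed.
#' @return List of class `pipeline_config`; invalid values raise errors.
#' @export
pipeline_config <- function(n_trim = 20L, min_coverage = 0.40, min_n = 100L,
                            outlier_threshold = 0.001, footprint = 10L,
                            total_ribosomes = 200000L, total_mrnas = 60000L,
                            include_zeros = FALSE, seed = 1L) {
  if (n_trim < 0) stop("n_trim must be nonnegative")
  if (min_coverage < 0 || min_coverage > 1) stop("min_coverage must be in [0, 1]")
  if (min_n < 1) stop("min_n must be positive")
  if (outlier_threshold <= 0) stop("outlier_threshold must be positive")
  if (footprint < 1) stop("footprint must be >= 1")
  if (total_ribosomes < 1 || total_mrnas < 1) {
    stop("pool sizes must be positive")
  }
  structure(list(n_trim = as.integer(n_trim), min_coverage = min_coverage,
                 min_n = as.integer(min_n),
                 outlier_threshold = outlier_threshold,
                 footprint = as.integer(footprint),
                 total_ribosomes = as.integer(total_ribosomes),
                 total_mrnas = as.integer(total_mrnas),
                 include_zeros = isTRUE(include_zeros),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run profiles through trimming, filtering, normalization and collection
#'
#' Convenience wrapper for stage 1 of the MTDR procedure: trim each
#' profile, keep the reference set by coverage, normalize to NFC, and pool
#' per-codon NFC samples.
#'
#' @param profiles List of raw profiles (see [read_profiles()]).
#' @param genome Named list of codon vectors.
#' @param config A [pipeline_config()].
#' @param blacklist Optional gene ids excluded before filtering (e.g.
#'   paralogous genes, which share a sequence and hence an MTDR).
#' @return List with `samples` (per time point, see [collect_codon_nfc()]),
#'   `reference` (the filtered, NFC-normalized profiles).
#' @export
profiles_to_samples <- function(profiles, genome, config = pipeline_config(),
                                blacklist = character(0)) {
  if (length(blacklist) > 0) {
    profiles <- Filter(function(p) !p$gene_id %in% blacklist, profiles)
  }
  trimmed <- lapply(profiles, trim_and_coverage, n_trim = config$n_trim)
  ref <- build_reference_set(trimmed, config$min_coverage)
  nfc <- Filter(Negate(is.null),
                lapply(ref, normalize_to_nfc,
                       include_zeros = config$include_zeros))
  samples <- collect_codon_nfc(nfc, genome, min_n = config$min_n)
  list(samples = samples, reference = nfc)
}
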