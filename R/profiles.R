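## Footprint count (RC) profiles: reading, trimming, coverage filtering,
## normalization to NFC, and per-codon NFC sample collection.  This is the
## first stage of the MTDR procedure: build a reliable reference set of
## profiles and turn it into per-codon decoding-time histograms.

#' Read codon-resolution footprint count profiles from TSV
#'
#' Expected columns (tab-separated, with header): `gene_id`, `time_point`,
#' `counts`, where `counts` is a comma-joined vector of nonnegative integer
#' footprint counts, one per codon of the CDS (position 1 = first codon).
#'
#' @param path Path to the TSV file.
#' @return A list of profiles; each element is a list with `gene_id`,
#'   `time_point` and integer `counts`.  Malformed rows raise errors naming
#'   the offending line.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("gene_id", "time_point", "counts")
  if (!all(need %in% names(tab))) {
    stop("profile TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    warning("empty profile file: ", path)
    return(list())
  }
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    raw <- strsplit(tab$counts[i], ",", fixed = TRUE)[[1]]
    cnt <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.finite(cnt) | cnt < 0 | cnt != floor(cnt))
    if (length(bad) > 0) {
      stop(sprintf("line %d (gene %s): invalid count '%s' at position %d",
                   i + 1L, tab$gene_id[i], raw[bad[1]], bad[1]))
    }
    out[[i]] <- list(gene_id = tab$gene_id[i], time_point = tab$time_point[i],
                     counts = as.integer(cnt))
  }
  out
}

#' Write profiles to TSV
#'
#' @param profiles List of profiles as returned by [read_profiles()] or
#'   [simulate_profiles()].
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(
    gene_id = vapply(profiles, `[[`, "", "gene_id"),
    time_point = vapply(profiles, `[[`, "", "time_point"),
    counts = vapply(profiles, function(p) paste(p$counts, collapse = ","), ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trim profile ends and compute coverage
#'
#' The first and last `n_trim` codons are excluded from each profile (they
#' carry initiation/termination-related biases); coverage is the fraction of
#' remaining positions with at least one footprint.
#'
#' @param profile A profile (list with `counts`).
#' @param n_trim Number of codons masked at each end (default 20).
#' @return The profile with added fields `window` (integer indices of
#'   unmasked positions), `coverage`, and `usable` (`FALSE` when the CDS is
#'   too short to survive trimming).
#' @export
trim_and_coverage <- function(profile, n_trim = 20) {
  L <- length(profile$counts)
  if (L <= 2 * n_trim) {
    profile$window <- integer(0)
    profile$coverage <- NA_real_
    profile$usable <- FALSE
    return(profile)
  }
  w <- (n_trim + 1L):(L - n_trim)
  profile$window <- w
  profile$coverage <- mean(profile$counts[w] > 0)
  profile$usable <- TRUE
  profile
}

#' Build the reference set of well-covered profiles
#'
#' @param profiles List of trimmed profiles (see [trim_and_coverage()]).
#' @param min_coverage Inclusive coverage threshold (default 0.40).
#' @return The profiles with `coverage >= min_coverage`; warns when a time
#'   point retains no profile.
#' @export
build_reference_set <- function(profiles, min_coverage = 0.40) {
  if (min_coverage < 0 || min_coverage > 1) {
    stop("min_coverage must be in [0, 1]")
  }
  keep <- vapply(profiles, function(p) {
    isTRUE(p$usable) && is.finite(p$coverage) && p$coverage >= min_coverage
  }, logical(1))
  res <- profiles[keep]
  tps <- unique(vapply(profiles, `[[`, "", "time_point"))
  kept_tps <- unique(vapply(res, `[[`, "", "time_point"))
  lost <- setdiff(tps, kept_tps)
  if (length(lost) > 0) {
    warning("no reference profiles at time point(s): ", paste(lost, collapse = ", "))
  }
  res
}

#' Normalize a trimmed profile to NFC
#'
#' Each profile is divided by its average footprint count so that profiles
#' from genes with different mRNA levels and initiation rates become
#' comparable.  By default the average is taken over covered (count > 0)
#' unmasked positions and NFC values are defined only there, since a zero
#' count cannot distinguish fast decoding from an unmapped position; set
#' `include_zeros = TRUE` to average over all unmasked positions instead.
#'
#' @param profile A trimmed, usable profile.
#' @param include_zeros Include zero-count positions in the average and the
#'   output (default `FALSE`).
#' @return The profile with an `nfc` field: a numeric vector aligned with
#'   the full CDS, `NA` outside the trimming window (and at uncovered
#'   positions unless `include_zeros`); `NULL` with a warning if the profile
#'   has no covered position.
#' @export
normalize_to_nfc <- function(profile, include_zeros = FALSE) {
  if (!isTRUE(profile$usable)) stop("profile not usable (too short to trim)")
  w <- profile$window
  cw <- profile$counts[w]
  covered <- cw > 0
  if (!any(covered)) {
    warning("all-zero profile dropped: ", profile$gene_id,
            " @ ", profile$time_point)
    return(NULL)
  }
  nfc <- rep(NA_real_, length(profile$counts))
  if (include_zeros) {
    nfc[w] <- cw / mean(cw)
  } else {
    nfc[w[covered]] <- cw[covered] / mean(cw[covered])
  }
  profile$nfc <- nfc
  profile
}

#' Collect per-codon NFC samples
#'
#' Walks every NFC profile of the reference set, looks up the codon at each
#' position with a defined NFC value, and pools the values per codon and
#' time point.  Codons observed fewer than `min_n` times at a time point are
#' not admitted to distribution fitting.
#'
#' @param nfc_profiles List of profiles carrying `nfc` (see
#'   [normalize_to_nfc()]).
#' @param genome Named list of codon vectors (see [generate_genome()]); must
#'   contain every profiled gene with matching CDS length.
#' @param min_n Minimum occurrences for admission (default 100).
#' @return Named list by time point; each element is a list with `values`
#'   (named list codon -> numeric vector, admitted codons only), `n` (named
#'   integer vector over all observed codons) and `excluded` (codons with
#'   `0 < n < min_n`).
#' @export
collect_codon_nfc <- function(nfc_profiles, genome, min_n = 100) {
  tps <- unique(vapply(nfc_profiles, `[[`, "", "time_point"))
  out <- list()
  for (tp in tps) {
    pool <- list()
    for (p in nfc_profiles) {
      if (p$time_point != tp || is.null(p$nfc)) next
      codons <- genome[[p$gene_id]]
      if (is.null(codons)) stop("gene missing from genome: ", p$gene_id)
      if (length(codons) != length(p$counts)) {
        stop("profile/CDS length mismatch for gene ", p$gene_id)
      }
      ok <- which(!is.na(p$nfc))
      if (length(ok) == 0) next
      pool[[length(pool) + 1L]] <- list(codon = codons[ok], nfc = p$nfc[ok])
    }
    if (length(pool) == 0) {
      out[[tp]] <- list(values = list(), n = integer(0), excluded = character(0))
      next
    }
    cod <- unlist(lapply(pool, `[[`, "codon"), use.names = FALSE)
    val <- unlist(lapply(pool, `[[`, "nfc"), use.names = FALSE)
    values <- split(val, cod)
    n <- vapply(values, length, integer(1))
    admitted <- names(values)[n >= min_n]
    out[[tp]] <- list(values = values[admitted], n = n,
                      excluded = setdiff(names(values), admitted))
  }
  out
}
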