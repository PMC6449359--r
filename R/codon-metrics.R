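## Static codon-usage indices and dynamic codon statistics: tRNA adaptation
## index, CAI-extreme codon groups, rank-based coefficient of variation,
## per-amino-acid weighted TDR, transcript-weighted codon demand, and the
## equal-sample-size control.

revcomp3 <- function(codon) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(codon, ""), function(b) paste(rev(comp[b]), collapse = ""), "")
}

#' tRNA adaptation index weights from tRNA gene copy numbers
#'
#' For each codon, the absolute adaptiveness is
#' `W = sum_j (1 - s_j) * tGCN_j` over the anticodons that can decode it
#' (Watson-Crick plus one wobble pairing determined by the codon's third
#' base); relative weights are `w = W / max(W)`.  Codons with `W = 0` are
#' assigned the geometric mean of the nonzero weights and flagged.
#'
#' @param tgcn Named numeric vector: tRNA gene copy number per anticodon
#'   (DNA alphabet); absent anticodons count as 0.
#' @param s_values Named selective-constraint vector for the wobble
#'   pairings, entries `WC` (Watson-Crick), `GU` (anticodon G : codon U),
#'   `IC` (inosine : C), `IA` (inosine : A), `UG` (anticodon U : codon G),
#'   each between 0 and 1.  Defaults are the standard published values (see
#'   `inst/extdata/tai_s_values.tsv`).
#' @return Named 61-vector of weights in (0, 1] with attribute `fallback`
#'   listing zero-W codons.
#' @export
compute_tai <- function(tgcn, s_values = c(WC = 0, GU = 0.41, IC = 0.28,
                                           IA = 0.9999, UG = 0.68)) {
  stopifnot(all(s_values >= 0), all(s_values <= 1))
  if (all(tgcn <= 0)) stop("all-zero tRNA gene copy numbers")
  codons <- sense_codons()
  cn <- function(ac) ifelse(is.na(tgcn[ac]), 0, tgcn[ac])
  third <- substr(codons, 3, 3)
  # the wobble anticodon is the WC anticodon of the sibling codon that the
  # same tRNA also reads through its wobble position
  W <- numeric(61)
  names(W) <- codons
  for (i in seq_along(codons)) {
    b <- third[i]
    stem <- substr(codons[i], 1, 2)
    if (b == "T") {          # WC: A-start anticodon; wobble: G-start (G:U)
      W[i] <- (1 - s_values["WC"]) * cn(revcomp3(paste0(stem, "T"))) +
              (1 - s_values["GU"]) * cn(revcomp3(paste0(stem, "C")))
    } else if (b == "C") {   # WC: G-start; wobble: A-start read as inosine (I:C)
      W[i] <- (1 - s_values["WC"]) * cn(revcomp3(paste0(stem, "C"))) +
              (1 - s_values["IC"]) * cn(revcomp3(paste0(stem, "T")))
    } else if (b == "A") {   # WC: T-start; wobble: A-start inosine (I:A)
      W[i] <- (1 - s_values["WC"]) * cn(revcomp3(paste0(stem, "A"))) +
              (1 - s_values["IA"]) * cn(revcomp3(paste0(stem, "T")))
    } else {                 # WC: C-start; wobble: T-start (U:G)
      W[i] <- (1 - s_values["WC"]) * cn(revcomp3(paste0(stem, "G"))) +
              (1 - s_values["UG"]) * cn(revcomp3(paste0(stem, "A")))
    }
  }
  if (max(W) <= 0) stop("no codon has positive adaptiveness")
  w <- W / max(W)
  zero <- names(w)[w == 0]
  if (length(zero) > 0) {
    w[zero] <- exp(mean(log(w[w > 0])))
  }
  attr(w, "fallback") <- zero
  w
}

#' High/Low CAI codon groups
#'
#' Per amino acid, the codons with maximal and minimal CAI form the High and
#' Low groups; methionine and tryptophan are excluded since their single
#' codon has no synonymous counterpart.  Ties are broken lexicographically
#' and recorded.
#'
#' @param cai Named numeric vector of per-codon CAI over the 61 sense
#'   codons.
#' @return List with `high` and `low` codon sets (18 codons each under the
#'   standard code) and `ties` (amino acids where a tie-break applied).
#' @export
select_cai_groups <- function(cai) {
  codons <- sense_codons()
  if (!all(codons %in% names(cai))) stop("cai must cover all 61 sense codons")
  fam <- synonymous_families()
  fam <- fam[!names(fam) %in% c("M", "W")]
  ties <- character(0)
  pick <- function(cs, which_max) {
    v <- cai[cs]
    tgt <- if (which_max) max(v) else min(v)
    hits <- sort(cs[v == tgt])
    if (length(hits) > 1) ties <<- union(ties, codon_to_aa()[hits[1]])
    hits[1]
  }
  high <- vapply(fam, pick, "", which_max = TRUE)
  low <- vapply(fam, pick, "", which_max = FALSE)
  list(high = unname(high), low = unname(low), ties = ties)
}

#' Coefficient of variation of a codon's TDR ranks across time points
#'
#' `CV = 100 * sd(ranks) / mean(ranks)`; a rank-stable codon has CV near 0,
#' a codon whose position in the decoding-rate order fluctuates has a large
#' CV.
#'
#' @param ranks Numeric rank trajectory (>= 2 finite values).
#' @param sd_type `"sample"` (n-1, default) or `"population"`.
#' @return CV in percent.
#' @export
rank_cv <- function(ranks, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ranks <- ranks[is.finite(ranks)]
  if (length(ranks) < 2) stop("need >= 2 fitted time points")
  s <- stats::sd(ranks)
  if (sd_type == "population") s <- s * sqrt((length(ranks) - 1) / length(ranks))
  100 * s / mean(ranks)
}

#' Per-amino-acid average TDR
#'
#' `TDR_AA = sum_i w_i * TDR_i` over the amino acid's synonymous codons,
#' with `w_i` the normalized genomic frequency of codon `i`.  Weights are
#' renormalized over fitted codons; a family with no fitted codon gives a
#' missing cell.
#'
#' @param tdr 61 x T TDR matrix.
#' @param genomic_freqs Named per-codon occurrence counts (weights are
#'   normalized within each family).
#' @return 20 x T matrix (rows = one-letter amino acids).
#' @export
amino_acid_tdr <- function(tdr, genomic_freqs) {
  fam <- synonymous_families()
  tps <- colnames(tdr)
  out <- matrix(NA_real_, length(fam), length(tps),
                dimnames = list(names(fam), tps))
  for (aa in names(fam)) {
    cs <- fam[[aa]]
    wts <- genomic_freqs[cs]
    wts[is.na(wts)] <- 0
    for (tp in tps) {
      v <- tdr[cs, tp]
      ok <- !is.na(v) & wts > 0
      if (!any(ok)) next
      w <- wts[ok] / sum(wts[ok])
      out[aa, tp] <- sum(w * v[ok])
    }
  }
  out
}

#' Transcript-weighted codon demand at one time point
#'
#' Each codon's occurrences per gene are weighted by the gene's transcript
#' level (RPKM) and summed over genes; the totals are then normalized within
#' each synonymous family, so demand fractions sum to 1 per amino acid.
#'
#' @param genome Named list of codon vectors.
#' @param rpkm Named per-gene transcript levels at the time point; genes
#'   with missing values are skipped.
#' @return List with `raw` (weighted totals per codon) and `demand`
#'   (within-family fractions; NA for families with zero total weight).
#' @export
codon_demand <- function(genome, rpkm) {
  codons <- sense_codons()
  raw <- stats::setNames(numeric(61), codons)
  for (g in names(genome)) {
    w <- rpkm[g]
    if (is.null(w) || is.na(w)) next
    if (w < 0) stop("negative rpkm for gene ", g)
    tab <- table(genome[[g]])
    raw[names(tab)] <- raw[names(tab)] + as.numeric(tab) * w
  }
  demand <- raw
  for (cs in synonymous_families()) {
    tot <- sum(raw[cs])
    demand[cs] <- if (tot > 0) raw[cs] / tot else NA_real_
  }
  list(raw = raw, demand = demand)
}

#' Vegetative-versus-time-point demand ratios, standardized per codon
#'
#' `ratio[c, t] = demand[c, veg] / demand[c, t]`, then divided per codon by
#' its mean over time points, so stage-specific shifts stand out against
#' each codon's own baseline.
#'
#' @param demand 61 x T demand matrix (columns named by time point).
#' @param vegetative Column label of the vegetative reference time point.
#' @return 61 x T standardized ratio matrix (NA where the denominator is 0).
#' @export
demand_ratio <- function(demand, vegetative) {
  if (!vegetative %in% colnames(demand)) {
    stop("vegetative time point not in demand matrix: ", vegetative)
  }
  ratio <- demand[, vegetative] / demand
  ratio[!is.finite(ratio)] <- NA_real_
  ratio / rowMeans(ratio, na.rm = TRUE)
}

#' Subsample all codon NFC samples to a common size
#'
#' Control for the codon-to-codon variability in histogram size: every
#' admitted codon is subsampled (without replacement) to the maximum of 100
#' and the minimal admitted sample size at that time point.
#'
#' @param samples One time point's samples (element of
#'   [collect_codon_nfc()] output).
#' @param seed Integer seed (subsampling is deterministic given it).
#' @return The samples with every codon's `values` resized to the common
#'   size; codons whose sample is smaller are excluded and listed.
#' @export
equal_sample_control <- function(samples, seed = 1L) {
  ns <- vapply(samples$values, length, integer(1))
  if (length(ns) == 0) return(samples)
  size <- max(100L, min(ns))
  drop <- names(ns)[ns < size]
  keep <- setdiff(names(ns), drop)
  withr_seed(seed, {
    vals <- lapply(samples$values[keep], function(v) sample(v, size))
  })
  list(values = vals, n = stats::setNames(rep(size, length(keep)), keep),
       excluded = union(samples$excluded, drop), common_size = size)
}

#' Compare rank-CV between Low- and High-CAI codon groups
#'
#' Right-tailed Wilcoxon rank-sum test of the hypothesis that rarely used
#' (Low CAI) codons have larger CV in their TDR ranks than frequently used
#' (High CAI) codons.
#'
#' @param cv Named per-codon CV vector.
#' @param low_set,high_set Disjoint codon sets.
#' @return List with `median_low`, `median_high`, `p` (one-sided, low >
#'   high).
#' @export
cv_group_test <- function(cv, low_set, high_set) {
  if (length(intersect(low_set, high_set)) > 0) {
    stop("low and high codon groups overlap")
  }
  lo <- cv[low_set]; hi <- cv[high_set]
  lo <- lo[is.finite(lo)]; hi <- hi[is.finite(hi)]
  if (length(lo) == 0 || length(hi) == 0) stop("empty group after filtering")
  wt <- stats::wilcox.test(lo, hi, alternative = "greater", exact = FALSE)
  list(median_low = stats::median(lo), median_high = stats::median(hi),
       p = wt$p.value)
}
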