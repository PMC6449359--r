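## Downstream statistics: MTDR co-scores and their association with PPI
## edges, the direction randomization test (fraction of a gene set with
## z > 0 at a focal time point versus size-matched random sets), and the
## within-cluster protein-sequence similarity test via Smith-Waterman local
## alignment.

#' MTDR co-score matrix
#'
#' Pairwise Pearson correlation of gene MTDR trajectories across time
#' points (pairwise-complete values); pairs sharing fewer than 3 finite
#' time points, and genes with constant trajectories, give missing entries.
#'
#' @param mtdr gene x T MTDR (or z-score) matrix.
#' @param gene_subset Optional gene ids to restrict to.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
mtdr_coscore <- function(mtdr, gene_subset = NULL) {
  if (!is.null(gene_subset)) mtdr <- mtdr[gene_subset, , drop = FALSE]
  co <- suppressWarnings(stats::cor(t(mtdr), use = "pairwise.complete.obs"))
  fin <- is.finite(as.matrix(mtdr))
  shared <- fin %*% t(fin)
  co[shared < 3] <- NA_real_
  diag(co) <- 1
  co
}

#' Association between MTDR co-scores and a PPI network
#'
#' Compares the co-score distribution of interacting pairs against
#' non-interacting pairs (one-sided Wilcoxon rank-sum, edges > non-edges)
#' and correlates edge co-scores with interaction confidence (Spearman).
#' The non-edge background is all unordered pairs not in the edge list,
#' subsampled to at most `max_nonedges` with a fixed seed.
#'
#' @param co Co-score matrix from [mtdr_coscore()].
#' @param edges data.frame with `gene_a`, `gene_b`, `confidence`.
#' @param max_nonedges Cap on the non-edge background sample.
#' @param seed Seed for the background subsample.
#' @return List with `median_edge`, `median_nonedge`, `p` (one-sided),
#'   `spearman_rho`, `spearman_p`, `n_edges`.
#' @export
ppi_association_test <- function(co, edges, max_nonedges = 1e6, seed = 1L) {
  genes <- rownames(co)
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes &
    edges$gene_a != edges$gene_b
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0) stop("no PPI edges left after intersecting with co-score genes")
  ia <- match(edges$gene_a, genes); ib <- match(edges$gene_b, genes)
  edge_idx <- ifelse(ia < ib, (ib - 1) * length(genes) + ia,
                     (ia - 1) * length(genes) + ib)
  edge_co <- co[cbind(ia, ib)]
  ut <- which(upper.tri(co))
  non_idx <- setdiff(ut, edge_idx)
  withr_seed(seed, {
    if (length(non_idx) > max_nonedges) {
      non_idx <- sample(non_idx, max_nonedges)
    }
  })
  non_co <- co[non_idx]
  edge_co_f <- edge_co[is.finite(edge_co)]
  non_co_f <- non_co[is.finite(non_co)]
  wt <- stats::wilcox.test(edge_co_f, non_co_f, alternative = "greater",
                           exact = FALSE)
  fin <- is.finite(edge_co) & is.finite(edges$confidence)
  ct <- suppressWarnings(
    stats::cor.test(edge_co[fin], edges$confidence[fin], method = "spearman",
                    exact = FALSE))
  list(median_edge = stats::median(edge_co_f),
       median_nonedge = stats::median(non_co_f),
       p = wt$p.value,
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       n_edges = nrow(edges))
}

#' Direction randomization test on per-gene z-scores
#'
#' Observed statistic: percent of the gene set with `z > 0` at the focal
#' time point.  The null draws `n_rand` size-matched gene sets uniformly
#' without replacement from all scored genes; the empirical p-value uses
#' the add-one convention `p = (1 + #(rand >= obs)) / (n_rand + 1)`.
#'
#' @param z Named per-gene z-scores at the focal time point.
#' @param gene_set Gene ids (subset of `names(z)`).
#' @param n_rand Number of randomizations (default 100).
#' @param seed Integer seed.
#' @return List with `observed_pct`, `random_mean`, `random_sd`, `p`.
#' @export
direction_randomization_test <- function(z, gene_set, n_rand = 100L,
                                         seed = 1L) {
  z <- z[is.finite(z)]
  universe <- names(z)
  if (!all(gene_set %in% universe)) stop("gene_set contains unscored genes")
  k <- length(gene_set)
  if (k > length(universe)) stop("gene_set larger than scored universe")
  obs <- 100 * mean(z[gene_set] > 0)
  withr_seed(seed, {
    rnd <- vapply(seq_len(n_rand), function(i) {
      100 * mean(z[sample(universe, k)] > 0)
    }, 0)
  })
  list(observed_pct = obs, random_mean = mean(rnd), random_sd = stats::sd(rnd),
       p = (1 + sum(rnd >= obs)) / (n_rand + 1))
}

#' Pairwise Smith-Waterman local alignment scores
#'
#' BLOSUM62 with gap open 11 / extend 1 (standard protein defaults).
#'
#' @param seqs Character vector (or `AAStringSet`) of amino-acid sequences,
#'   named.
#' @param gap_open,gap_extend Gap penalties (positive).
#' @return Symmetric matrix of local alignment scores (self-scores on the
#'   diagonal).
#' @export
alignment_score_matrix <- function(seqs, gap_open = 11, gap_extend = 1) {
  if (!methods::is(seqs, "AAStringSet")) {
    seqs <- Biostrings::AAStringSet(seqs)
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  n <- length(seqs)
  m <- matrix(NA_real_, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      seqs[i:n], seqs[[i]], type = "local", substitutionMatrix = sub,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
    m[i, i:n] <- sc
    m[i:n, i] <- sc
  }
  m
}

#' Within-cluster protein similarity versus random gene groups
#'
#' Mean pairwise local-alignment score within the cluster, compared with
#' `n_rand` size-matched random groups drawn from the universe; empirical
#' p-value with the add-one convention.
#'
#' @param cluster Gene ids (>= 2) within `universe`.
#' @param universe Named amino-acid sequences (character or `AAStringSet`),
#'   or `NULL` when `scores` is supplied.
#' @param n_rand Number of random groups.
#' @param seed Integer seed.
#' @param scores Optional precomputed score matrix from
#'   [alignment_score_matrix()] covering the universe (computed from
#'   `universe` if missing).
#' @return List with `mean_score`, `random_mean`, `random_sd`, `p`.
#' @export
cluster_alignment_similarity <- function(cluster, universe = NULL,
                                         n_rand = 100L, seed = 1L,
                                         scores = NULL) {
  if (is.null(scores)) {
    if (is.null(universe)) stop("need either universe sequences or scores")
    if (is.character(universe) &&
        any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", universe))) {
      stop("invalid residue in sequences")
    }
    scores <- alignment_score_matrix(universe)
  }
  ids <- rownames(scores)
  if (length(cluster) < 2) stop("cluster needs >= 2 sequences")
  if (!all(cluster %in% ids)) stop("cluster ids missing from universe")
  mean_pair <- function(g) {
    s <- scores[g, g]
    mean(s[upper.tri(s)])
  }
  obs <- mean_pair(cluster)
  k <- length(cluster)
  withr_seed(seed, {
    rnd <- vapply(seq_len(n_rand), function(i) mean_pair(sample(ids, k)), 0)
  })
  list(mean_score = obs, random_mean = mean(rnd), random_sd = stats::sd(rnd),
       p = (1 + sum(rnd >= obs)) / (n_rand + 1))
}
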