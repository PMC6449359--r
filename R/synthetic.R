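## Synthetic study generator: genomes, ground-truth dynamic codon decoding
## rates, ribo-seq-like count profiles, transcript levels and PPI networks
## with the statistical structure the downstream estimators assume, so the
## whole pipeline can be exercised and validated without external data.
##
## The generative model mirrors the estimator's decomposition: a codon's
## dwell signal is 1/rate (the typical component) plus, with probability
## pause_prob, an exponential excess (pauses / traffic jams); observed
## counts are Poisson around the scaled dwell signal.

#' Generate a synthetic genome of in-frame coding sequences
#'
#' Codons are drawn independently from `codon_usage`; only sense codons are
#' used, so no internal stops can occur.  Lengths are uniform over
#' `length_range` (minimum 45 codons so that end-trimming leaves positions).
#'
#' @param n_genes Number of genes.
#' @param length_range Integer vector `c(min, max)` CDS length in codons.
#' @param codon_usage Nonnegative weight per sense codon (named 61-vector or
#'   unnamed in [sense_codons()] order); default uniform.  Every amino-acid
#'   family must have at least one positive weight.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Named list `g0001`, ... of character codon vectors.
#' @export
generate_genome <- function(n_genes, length_range = c(150L, 450L),
                            codon_usage = NULL, seed = 1L) {
  codons <- sense_codons()
  if (is.null(codon_usage)) codon_usage <- rep(1, 61)
  if (is.null(names(codon_usage))) names(codon_usage) <- codons
  codon_usage <- codon_usage[codons]
  if (any(!is.finite(codon_usage)) || any(codon_usage < 0)) {
    stop("codon_usage weights must be finite and nonnegative")
  }
  fam <- synonymous_families()
  dead <- names(fam)[vapply(fam, function(cs) sum(codon_usage[cs]) <= 0, logical(1))]
  if (length(dead) > 0) {
    stop("codon_usage has no positive weight for amino acid(s): ",
         paste(dead, collapse = ", "))
  }
  if (length(length_range) != 2 || length_range[1] < 45) {
    stop("length_range must be c(min, max) with min >= 45 codons")
  }
  withr_seed(seed, {
    len_choices <- seq.int(length_range[1], length_range[2])
    lens <- len_choices[sample.int(length(len_choices), n_genes,
                                   replace = TRUE)]
    genome <- lapply(lens, function(L) {
      sample(codons, L, replace = TRUE, prob = codon_usage)
    })
  })
  names(genome) <- sprintf("g%04d", seq_len(n_genes))
  genome
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate ground-truth codon decoding-rate trajectories
#'
#' Rates follow the per-codon base rate with multiplicative log-normal noise
#' per time point.  Designated "inverted" codons emulate the observed
#' behaviour of rare codons whose decoding-rate rank flips from the bottom
#' to the top of the rank scale at specific stages: at their designated time
#' points they are placed above the column's 90th percentile, and below the
#' 10th percentile elsewhere.
#'
#' @param base_rates Positive 61-vector of per-codon rates (named by codon
#'   or in [sense_codons()] order).
#' @param n_timepoints Number of time points (>= 2).
#' @param inversion Optional list with `codons` (character) and `timepoints`
#'   (integer indices) marking the rank-inversion perturbation.
#' @param noise_sd Standard deviation of the log-normal rate noise.
#' @param seed Integer seed.
#' @return 61 x T matrix of strictly positive rates (rows named by codon).
#' @export
generate_rate_trajectories <- function(base_rates, n_timepoints,
                                       inversion = NULL, noise_sd = 0.1,
                                       seed = 1L) {
  codons <- sense_codons()
  if (is.null(names(base_rates))) names(base_rates) <- codons
  base_rates <- base_rates[codons]
  stopifnot(all(base_rates > 0), n_timepoints >= 2)
  withr_seed(seed, {
    m <- matrix(base_rates, nrow = 61, ncol = n_timepoints,
                dimnames = list(codons, paste0("t", seq_len(n_timepoints))))
    if (noise_sd > 0) {
      m <- m * exp(matrix(stats::rnorm(61 * n_timepoints, 0, noise_sd),
                          nrow = 61))
    }
    if (!is.null(inversion)) {
      inv <- inversion$codons
      its <- inversion$timepoints
      stopifnot(all(inv %in% codons))
      for (t in seq_len(n_timepoints)) {
        others <- m[setdiff(codons, inv), t]
        if (t %in% its) {
          m[inv, t] <- stats::quantile(others, 0.95) * (1 + 0.05 * seq_along(inv))
        } else {
          m[inv, t] <- stats::quantile(others, 0.05) * (1 - 0.05 * seq_along(inv))
        }
      }
    }
  })
  m
}

#' Generate per-gene transcript levels across time points
#'
#' Log-normal across genes (wide expression spread, as in real ribo-seq
#' compendia where coverage varies over orders of magnitude) with mild
#' log-normal temporal wobble around each gene's baseline.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_timepoints Number of time points.
#' @param meanlog,sdlog Parameters of the across-gene baseline log-normal
#'   (defaults give RPKM-like spread over ~3 orders of magnitude).
#' @param temporal_sd Log-sd of the per-time-point wobble.
#' @param seed Integer seed.
#' @return gene x T matrix of nonnegative levels.
#' @export
generate_transcript_levels <- function(gene_ids, n_timepoints,
                                       meanlog = 3, sdlog = 1.2,
                                       temporal_sd = 0.2, seed = 1L) {
  withr_seed(seed, {
    base <- stats::rlnorm(length(gene_ids), meanlog, sdlog)
    m <- base * exp(matrix(stats::rnorm(length(gene_ids) * n_timepoints,
                                        0, temporal_sd),
                           nrow = length(gene_ids)))
  })
  dimnames(m) <- list(gene_ids, paste0("t", seq_len(n_timepoints)))
  m
}

#' Assemble a synthetic ground truth
#'
#' @param codon_rates 61 x T rate matrix (see [generate_rate_trajectories()]).
#' @param transcript_levels gene x T matrix (see
#'   [generate_transcript_levels()]).
#' @param initiation_rates Positive per-gene rates (named).
#' @param pause_prob Probability a codon instance draws a pause excess.
#' @param pause_scale Mean of the exponential pause excess (in dwell units).
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(codon_rates, transcript_levels, initiation_rates,
                            pause_prob = 0.05, pause_scale = 1.0) {
  stopifnot(all(codon_rates > 0), pause_prob >= 0, pause_prob <= 1,
            pause_scale > 0, all(initiation_rates >= 0))
  structure(list(codon_rates = codon_rates,
                 transcript_levels = transcript_levels,
                 initiation_rates = initiation_rates,
                 pause_prob = pause_prob, pause_scale = pause_scale),
            class = "synthetic_truth")
}

#' Simulate codon-resolution footprint count profiles
#'
#' Per codon position, the dwell signal is `1/rate` plus, with probability
#' `pause_prob`, an exponential excess of mean `pause_scale`; the expected
#' count is proportional to the gene's transcript level times the dwell,
#' scaled so the mean count per codon over the data set equals `depth`;
#' observed counts are Poisson.
#'
#' @param genome Named list of codon vectors.
#' @param truth A [synthetic_truth()] object covering every genome gene.
#' @param depth Target mean reads per codon (> 0).
#' @param seed Integer seed.
#' @return List of profiles (gene x time point), each with `gene_id`,
#'   `time_point`, integer `counts`.
#' @export
simulate_profiles <- function(genome, truth, depth = 5, seed = 1L) {
  stopifnot(depth > 0)
  missing_genes <- setdiff(names(genome), rownames(truth$transcript_levels))
  if (length(missing_genes) > 0) {
    stop("genes absent from truth transcript levels: ",
         paste(utils::head(missing_genes, 3), collapse = ", "))
  }
  tps <- colnames(truth$codon_rates)
  out <- vector("list", length(genome) * length(tps))
  k <- 0L
  withr_seed(seed, {
    for (tp in tps) {
      rates <- truth$codon_rates[, tp]
      lv <- truth$transcript_levels[names(genome), tp]
      # scale so mean expected count per codon equals depth
      mean_dwell <- vapply(genome, function(cs) mean(1 / rates[cs]), 0)
      mean_dwell <- mean_dwell * (1 + truth$pause_prob * truth$pause_scale /
                                    mean_dwell)  # pause contribution
      scale <- depth / mean(lv * mean_dwell / mean(1 / rates))
      for (g in names(genome)) {
        cs <- genome[[g]]
        dwell <- 1 / rates[cs]
        np <- length(cs)
        pauses <- stats::rbinom(np, 1, truth$pause_prob) *
          stats::rexp(np, rate = 1 / truth$pause_scale)
        lambda <- scale * lv[g] * (dwell + pauses) / mean(1 / rates)
        k <- k + 1L
        out[[k]] <- list(gene_id = g, time_point = tp,
                         counts = stats::rpois(np, lambda))
      }
    }
  })
  out[seq_len(k)]
}

#' Generate a synthetic PPI edge list coupled to MTDR co-patterns
#'
#' With `signal > 0`, a fraction `signal` of edges is drawn among gene pairs
#' whose MTDR trajectories are highly correlated (top co-score quartile),
#' the rest uniformly at random; confidence scores increase with the pair's
#' co-score under signal and are uniform noise otherwise.
#'
#' @param genes Character vector of gene ids.
#' @param mtdr gene x T MTDR matrix covering `genes`.
#' @param signal Fraction of edges drawn among co-patterned pairs (0 to 1).
#' @param n_edges Number of edges to emit.
#' @param seed Integer seed.
#' @return data.frame with `gene_a`, `gene_b`, `confidence` in (0, 1]; no
#'   self-edges, no duplicate pairs.
#' @export
generate_ppi_network <- function(genes, mtdr, signal = 0.5, n_edges = 200,
                                 seed = 1L) {
  stopifnot(signal >= 0, signal <= 1)
  co <- stats::cor(t(mtdr[genes, , drop = FALSE]))
  pairs <- which(upper.tri(co), arr.ind = TRUE)
  cov_vals <- co[pairs]
  top <- which(cov_vals >= stats::quantile(cov_vals, 0.75, na.rm = TRUE))
  withr_seed(seed, {
    n_sig <- stats::rbinom(1, n_edges, signal)
    idx_sig <- if (n_sig > 0 && length(top) > 0) {
      sample(top, min(n_sig, length(top)))
    } else integer(0)
    rest <- setdiff(seq_len(nrow(pairs)), idx_sig)
    idx_bg <- sample(rest, min(n_edges - length(idx_sig), length(rest)))
    idx <- c(idx_sig, idx_bg)
    conf <- if (signal > 0) {
      r <- cov_vals[idx]
      pmin(pmax(stats::plogis(2 * r + stats::rnorm(length(idx), 0, 0.5)),
                1e-3), 1)
    } else {
      stats::runif(length(idx), 0.15, 1)
    }
  })
  data.frame(gene_a = genes[pairs[idx, 1]], gene_b = genes[pairs[idx, 2]],
             confidence = conf, stringsAsFactors = FALSE)
}

#' Write a genome to FASTA (appending a stop codon)
#'
#' @param genome Named list of codon vectors.
#' @param path Output FASTA path.
#' @param stop_codon Stop codon appended to each CDS (never profiled).
#' @export
write_genome_fasta <- function(genome, path, stop_codon = "TAA") {
  seqs <- Biostrings::DNAStringSet(vapply(genome, function(cs) {
    paste0(paste(cs, collapse = ""), stop_codon)
  }, ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an in-frame CDS FASTA into a codon-list genome
#'
#' Trailing stop codons are removed; internal stops or non-multiple-of-3
#' lengths are errors.
#'
#' @param path FASTA path.
#' @return Named list of codon vectors.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stops <- c("TAA", "TAG", "TGA")
  genome <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    if (nchar(s) %% 3 != 0) stop("CDS length not a multiple of 3: ", names(seqs)[i])
    cs <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (cs[length(cs)] %in% stops) cs <- cs[-length(cs)]
    if (any(cs %in% stops)) stop("internal stop codon in ", names(seqs)[i])
    cs
  })
  names(genome) <- sub("\\s.*", "", names(seqs))
  genome
}
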