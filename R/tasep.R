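## R surface over the C++ Gillespie TASEP engine: single-mRNA simulation,
## whole-cell simulation with a shared finite ribosome pool, synonymous
## recoding of gene clusters, translatome comparison, and a deterministic
## mean-field cross-check solver.

#' TASEP simulation configuration
#'
#' @param footprint Ribosome size in codons (default 10).
#' @param burn_in Simulated time discarded before averaging.
#' @param measure_time Averaging window (> 0).
#' @param seed Integer seed for the simulation RNG.
#' @return List of class `tasep_config`.
#' @export
tasep_config <- function(footprint = 10L, burn_in = 200, measure_time = 500,
                         seed = 1L) {
  stopifnot(footprint >= 1, measure_time > 0, burn_in >= 0)
  structure(list(footprint = as.integer(footprint), burn_in = burn_in,
                 measure_time = measure_time, seed = as.integer(seed)),
            class = "tasep_config")
}

#' Simulate translation of a single mRNA
#'
#' Continuous-time exclusion dynamics with an unlimited ribosome supply:
#' initiation at rate `ir` while the first `footprint` codons are vacant,
#' elongation of the ribosome at codon `i` at rate `rates[i]` while codon
#' `i + footprint` is vacant, termination at the last codon.  Statistics
#' are time averages over `measure_time` after `burn_in`.
#'
#' @param rates Positive per-codon elongation rates (length > footprint).
#' @param ir Initiation rate (>= 0).
#' @param cfg A [tasep_config()].
#' @param check_exclusion Assert the no-overlap invariant after every move
#'   (debugging; slows the simulation).
#' @return List with `mean_ribosomes`, `density` (per codon),
#'   `production_rate` (terminations per unit time), `events`,
#'   `exclusion_ok`.
#' @export
simulate_single_mrna <- function(rates, ir, cfg = tasep_config(),
                                 check_exclusion = FALSE) {
  stopifnot(all(rates > 0), ir >= 0, length(rates) > cfg$footprint)
  res <- .tasep_single_cpp(as.numeric(rates), ir, cfg$footprint, cfg$burn_in,
                           cfg$measure_time, cfg$seed, check_exclusion)
  list(mean_ribosomes = res$mean_ribosomes[1],
       density = res$mean_ribosomes[1] / length(rates),
       production_rate = res$production_rate[1],
       events = res$events, exclusion_ok = res$exclusion_ok)
}

#' Build a whole-cell translation state
#'
#' @param genome Named list of codon vectors.
#' @param codon_rates Named per-codon elongation rates (e.g. a TDR column).
#' @param copies Named per-gene mRNA copy numbers (integers >= 0); their sum
#'   should equal `total_mrnas` (a mismatch is tolerated with a warning).
#' @param ir Named per-gene initiation rates.
#' @param total_ribosomes Shared ribosome pool size (default 200000).
#' @param total_mrnas Expected total mRNA count (default 60000).
#' @return List of class `cell_state`.
#' @export
cell_state <- function(genome, codon_rates, copies, ir,
                       total_ribosomes = 200000L, total_mrnas = 60000L) {
  genes <- names(genome)
  stopifnot(all(genes %in% names(copies)), all(genes %in% names(ir)),
            total_ribosomes > 0)
  if (sum(copies[genes]) != total_mrnas) {
    warning("sum of mRNA copies (", sum(copies[genes]),
            ") differs from total_mrnas (", total_mrnas, ")")
  }
  structure(list(genome = genome, codon_rates = codon_rates,
                 copies = copies[genes], ir = ir[genes],
                 total_ribosomes = as.integer(total_ribosomes),
                 total_mrnas = as.integer(total_mrnas)),
            class = "cell_state")
}

#' Whole-cell translation simulation with a finite ribosome pool
#'
#' All mRNA copies share one ribosome pool; each mRNA's effective initiation
#' propensity is its initiation rate scaled by the free-pool fraction
#' (`coupling = "fraction"`, default) or by the absolute free count
#' (`"mass_action"`).  A terminating ribosome re-joins the free pool;
#' `free + bound = total` holds exactly at every event.
#'
#' @param cell A [cell_state()].
#' @param cfg A [tasep_config()].
#' @param coupling Pool coupling mode.
#' @param check_exclusion Assert the no-overlap invariant during simulation.
#' @return List with `free_pool` (time-averaged free ribosomes),
#'   `mean_translation_rate` (mean per-gene production rate),
#'   `per_gene` (data.frame: gene_id, copies, mean_ribosomes,
#'   production_rate summed over copies), `conservation_ok`,
#'   `exclusion_ok`, `pool_exhausted`.
#' @export
whole_cell_simulate <- function(cell, cfg = tasep_config(),
                                coupling = c("fraction", "mass_action"),
                                check_exclusion = FALSE) {
  coupling <- match.arg(coupling)
  genes <- names(cell$genome)
  gene_rates <- lapply(cell$genome, function(cs) {
    unname(cell$codon_rates[cs])
  })
  bad <- genes[vapply(gene_rates, function(r) any(!is.finite(r) | r <= 0),
                      logical(1))]
  if (length(bad) > 0) stop("missing/non-positive codon rate for gene(s): ",
                            paste(utils::head(bad, 3), collapse = ", "))
  gene_of <- rep(seq_along(genes) - 1L, times = cell$copies)
  ir_of <- rep(unname(cell$ir), times = cell$copies)
  res <- .tasep_cell_cpp(as.integer(gene_of), gene_rates, as.numeric(ir_of),
                         cfg$footprint, cfg$burn_in, cfg$measure_time,
                         cell$total_ribosomes,
                         if (coupling == "fraction") 1L else 2L,
                         cfg$seed, check_exclusion)
  if (res$pool_exhausted) {
    warning("free ribosome pool was exhausted during the simulation")
  }
  per_gene <- data.frame(
    gene_id = genes, copies = as.integer(cell$copies),
    mean_ribosomes = as.numeric(tapply(res$mean_ribosomes, gene_of, sum)),
    production_rate = as.numeric(tapply(res$production_rate, gene_of, sum)),
    stringsAsFactors = FALSE)
  list(free_pool = res$mean_free,
       mean_translation_rate = mean(per_gene$production_rate / per_gene$copies),
       per_gene = per_gene,
       conservation_ok = res$conservation_ok,
       exclusion_ok = res$exclusion_ok,
       pool_exhausted = res$pool_exhausted)
}

#' Synonymously recode a gene cluster by demand-weighted draws
#'
#' For each amino acid of each cluster gene, a synonymous codon is drawn
#' from `demand_weights` restricted to the amino acid's family; the protein
#' sequence is unchanged and non-cluster genes are untouched.
#'
#' @param genome Named list of codon vectors.
#' @param cluster Gene ids to recode (must exist in `genome`).
#' @param demand_weights Named per-codon weights (>= 0; at least one
#'   positive codon per family used by the cluster).
#' @param n_versions Number of recoded genomes (default 20).
#' @param seed Integer seed.
#' @return List of `n_versions` genomes.
#' @export
randomize_cluster_codons <- function(genome, cluster, demand_weights,
                                     n_versions = 20L, seed = 1L) {
  missing_ids <- setdiff(cluster, names(genome))
  if (length(missing_ids) > 0) {
    stop("cluster gene(s) absent from genome: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  fam <- synonymous_families()
  aa_of <- codon_to_aa()
  fam_w <- lapply(fam, function(cs) {
    w <- demand_weights[cs]
    w[is.na(w)] <- 0
    w
  })
  dead <- names(fam_w)[vapply(fam_w, sum, 0) <= 0]
  used_aa <- unique(unlist(lapply(genome[cluster], function(cs) aa_of[cs])))
  if (any(used_aa %in% dead)) {
    stop("demand_weights has no positive codon for amino acid(s): ",
         paste(intersect(used_aa, dead), collapse = ", "))
  }
  withr_seed(seed, {
    versions <- lapply(seq_len(n_versions), function(v) {
      g2 <- genome
      for (g in cluster) {
        aas <- aa_of[g2[[g]]]
        g2[[g]] <- vapply(aas, function(a) {
          cs <- fam[[a]]
          if (length(cs) == 1) cs else sample(cs, 1, prob = fam_w[[a]])
        }, "", USE.NAMES = FALSE)
      }
      g2
    })
  })
  versions
}

#' Compare an original translatome with randomized recodings
#'
#' Percent change is `100 * (mean_rand - original) / original`; the z-score
#' is `(original - mean_rand) / sd_rand`, so a positive z with a negative
#' percent change means the randomized genomes translate worse than the
#' original.
#'
#' @param original Whole-cell result (list with `free_pool`,
#'   `mean_translation_rate`).
#' @param randomized List (length >= 2) of whole-cell results.
#' @return List with `pct_change_free_pool`, `z_free`,
#'   `pct_change_mean_rate`, `z_rate`.
#' @export
compare_translatome <- function(original, randomized) {
  stopifnot(length(randomized) >= 2)
  fp <- vapply(randomized, `[[`, 0, "free_pool")
  tr <- vapply(randomized, `[[`, 0, "mean_translation_rate")
  zstat <- function(orig, rnd) {
    s <- stats::sd(rnd)
    if (s == 0) {
      warning("zero variance across randomizations; z undefined")
      return(NA_real_)
    }
    (orig - mean(rnd)) / s
  }
  list(pct_change_free_pool = 100 * (mean(fp) - original$free_pool) /
         original$free_pool,
       z_free = zstat(original$free_pool, fp),
       pct_change_mean_rate = 100 * (mean(tr) - original$mean_translation_rate) /
         original$mean_translation_rate,
       z_rate = zstat(original$mean_translation_rate, tr))
}

#' Deterministic mean-field steady state of a single TASEP mRNA
#'
#' Fixed-point iteration on per-codon densities under the standard
#' mean-field factorization of the exclusion process with extended
#' particles; used as a fast independent cross-check of the stochastic
#' simulator's occupancy and flux.
#'
#' @param rates Positive per-codon rates.
#' @param ir Initiation rate.
#' @param footprint Ribosome size in codons.
#' @param max_iter,tol Iteration controls.
#' @return List with `mean_ribosomes` and `production_rate` (flux).
#' @export
mean_field_single_mrna <- function(rates, ir, footprint = 10L,
                                   max_iter = 20000L, tol = 1e-10) {
  L <- length(rates)
  rho <- rep(0, L)  # ribosome (A-site) density per codon
  damp <- 0.2
  for (it in seq_len(max_iter)) {
    # coverage ahead of codon i: probability codon i+fp is inside some footprint
    cover <- stats::filter(c(rho, rep(0, footprint)), rep(1, footprint),
                           sides = 1)
    cover <- pmin(as.numeric(cover)[seq_len(L + footprint)], 1)
    block <- c(cover[(1 + footprint):(L + footprint)])  # occupancy of i+fp.. window
    flux_in <- ir * max(0, 1 - cover[footprint])
    new_rho <- rho
    # local balance: flux through codon i approximates rates[i]*rho[i]*(1-block[i])
    flux <- rates * rho * pmax(1 - block, 0)
    # relax densities toward flux balance with the entry flux
    target_flux <- flux_in
    adj <- rho
    for (i in seq_len(L)) {
      out_cap <- rates[i] * pmax(1 - block[i], 1e-12)
      adj[i] <- target_flux / out_cap
    }
    adj <- pmin(adj, 1 / footprint)
    new_rho <- (1 - damp) * rho + damp * adj
    if (max(abs(new_rho - rho)) < tol) {
      rho <- new_rho
      break
    }
    rho <- new_rho
  }
  list(mean_ribosomes = sum(rho),
       production_rate = rates[L] * rho[L])
}
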