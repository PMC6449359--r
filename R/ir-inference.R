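## Initiation-rate inference by inverting the TASEP: map a footprint
## density to an expected ribosome count via monotone linear interpolation
## through occupancy anchors, then binary-search the initiation rate whose
## simulated mean ribosome count matches the target.  Every simulation in
## one search uses the same RNG seed (common random numbers), which keeps
## the simulated count effectively monotone in ir and the bisection sound.

#' Build an occupancy anchor from density/ribosome pairs
#'
#' @param density Strictly increasing RPKM-like footprint densities.
#' @param ribosomes Nondecreasing expected ribosome counts.
#' @return List of class `occupancy_anchor`.
#' @export
occupancy_anchor <- function(density, ribosomes) {
  if (length(density) < 2) stop("anchor needs >= 2 points")
  if (any(diff(density) <= 0)) stop("densities must be strictly increasing")
  if (any(diff(ribosomes) < 0)) stop("ribosome counts must be nondecreasing")
  structure(list(density = as.numeric(density),
                 ribosomes = as.numeric(ribosomes)),
            class = "occupancy_anchor")
}

#' Pool per-gene occupancy data into binned median anchors
#'
#' @param density Per-gene footprint densities (vegetative time point).
#' @param ribosomes Per-gene expected ribosome counts.
#' @param n_bins Number of quantile bins.
#' @return An [occupancy_anchor()] over binned medians (bins merged where
#'   needed to keep the mapping monotone).
#' @export
pooled_anchor <- function(density, ribosomes, n_bins = 10L) {
  ok <- is.finite(density) & is.finite(ribosomes)
  density <- density[ok]; ribosomes <- ribosomes[ok]
  br <- unique(stats::quantile(density, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(density, br, include.lowest = TRUE)
  d <- as.numeric(tapply(density, bin, stats::median))
  r <- as.numeric(tapply(ribosomes, bin, stats::median))
  keep <- !is.na(d) & !is.na(r)
  d <- d[keep]; r <- r[keep]
  r <- cummax(r)  # enforce monotonicity on the pooled medians
  occupancy_anchor(d, r)
}

#' Map a footprint density to an expected ribosome count
#'
#' Piecewise-linear interpolation through the anchor points; queries outside
#' the anchor range are linearly extrapolated from the nearest segment and
#' flagged.
#'
#' @param density Numeric query (vectorized).
#' @param anchor An [occupancy_anchor()].
#' @return Numeric vector with attribute `extrapolated` (logical vector).
#' @export
map_density_to_ribosomes <- function(density, anchor) {
  d <- anchor$density; r <- anchor$ribosomes
  n <- length(d)
  out <- stats::approx(d, r, xout = density, rule = 2)$y
  lo <- density < d[1]
  hi <- density > d[n]
  if (any(lo)) {
    s <- (r[2] - r[1]) / (d[2] - d[1])
    out[lo] <- r[1] + s * (density[lo] - d[1])
  }
  if (any(hi)) {
    s <- (r[n] - r[n - 1]) / (d[n] - d[n - 1])
    out[hi] <- r[n] + s * (density[hi] - d[n])
  }
  attr(out, "extrapolated") <- lo | hi
  out
}

#' Infer an mRNA's initiation rate by binary search against the TASEP
#'
#' Grows an upper bracket geometrically until the simulated mean ribosome
#' count exceeds the target (or a jamming plateau is detected), then
#' bisects.  All simulations reuse `cfg$seed`.
#'
#' @param rates Positive per-codon elongation rates.
#' @param target_ribosomes Target mean ribosome count (>= 0); values above
#'   the hard packing cap are clipped and flagged.
#' @param cfg A [tasep_config()].
#' @param tol Convergence tolerance in ribosomes (default
#'   `max(0.1, 0.05 * target)`).
#' @param max_iter Maximum bisection iterations (default 40).
#' @param ir_init Initial upper-bracket guess.
#' @return List with `ir`, `achieved_ribosomes`, `iterations`, `status`
#'   (`"ok"` / `"unconverged"`), `clipped`.
#' @export
infer_initiation_rate <- function(rates, target_ribosomes, cfg = tasep_config(),
                                  tol = NULL, max_iter = 40L,
                                  ir_init = NULL) {
  stopifnot(target_ribosomes >= 0)
  if (target_ribosomes == 0) {
    return(list(ir = 0, achieved_ribosomes = 0, iterations = 0L,
                status = "ok", clipped = FALSE))
  }
  cap <- floor(length(rates) / cfg$footprint)
  clipped <- FALSE
  if (target_ribosomes > cap) {
    target_ribosomes <- cap
    clipped <- TRUE
  }
  if (is.null(tol)) tol <- max(0.1, 0.05 * target_ribosomes)
  sim <- function(ir) {
    simulate_single_mrna(rates, ir, cfg)$mean_ribosomes
  }
  # grow the bracket
  hi <- if (is.null(ir_init)) min(rates) / cfg$footprint else ir_init
  val_hi <- sim(hi)
  grow <- 0L
  while (val_hi < target_ribosomes && grow < 40L) {
    prev <- val_hi
    hi <- hi * 2
    val_hi <- sim(hi)
    grow <- grow + 1L
    # plateau: doubling ir no longer raises occupancy appreciably
    if (val_hi < target_ribosomes && val_hi - prev < 1e-3 * max(1, prev)) {
      return(list(ir = hi, achieved_ribosomes = val_hi, iterations = grow,
                  status = "unconverged", clipped = clipped))
    }
  }
  if (val_hi < target_ribosomes) {
    return(list(ir = hi, achieved_ribosomes = val_hi, iterations = grow,
                status = "unconverged", clipped = clipped))
  }
  lo <- 0; val <- val_hi; ir <- hi
  iter <- 0L
  while (iter < max_iter) {
    mid <- (lo + hi) / 2
    val <- sim(mid)
    ir <- mid
    iter <- iter + 1L
    if (abs(val - target_ribosomes) <= tol) break
    if (val < target_ribosomes) lo <- mid else hi <- mid
  }
  status <- if (abs(val - target_ribosomes) <= tol) "ok" else "unconverged"
  list(ir = ir, achieved_ribosomes = val, iterations = iter, status = status,
       clipped = clipped)
}

#' Infer initiation rates for a set of genes at one time point
#'
#' Genes without a footprint profile at the time point get status
#' `"no_profile"` and no rate.
#'
#' @param genome Named list of codon vectors.
#' @param codon_rates Named per-codon elongation rates at the time point.
#' @param targets Named per-gene target ribosome counts (NA = no profile).
#' @param cfg A [tasep_config()].
#' @param ... Passed to [infer_initiation_rate()].
#' @return data.frame: gene_id, ir, achieved_ribosomes, iterations, status.
#' @export
infer_ir_table <- function(genome, codon_rates, targets,
                           cfg = tasep_config(), ...) {
  rows <- lapply(names(genome), function(g) {
    tgt <- targets[g]
    if (is.null(tgt) || is.na(tgt)) {
      return(data.frame(gene_id = g, ir = NA_real_,
                        achieved_ribosomes = NA_real_, iterations = 0L,
                        status = "no_profile", stringsAsFactors = FALSE))
    }
    rates <- unname(codon_rates[genome[[g]]])
    r <- infer_initiation_rate(rates, tgt, cfg, ...)
    data.frame(gene_id = g, ir = r$ir, achieved_ribosomes = r$achieved_ribosomes,
               iterations = r$iterations, status = r$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
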