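# Stochastic TASEP: limiting regimes, exclusion, conservation, recoding.

test_that("zero initiation gives an empty lattice", {
  r <- simulate_single_mrna(rep(1, 100), ir = 0,
                            tasep_config(burn_in = 50, measure_time = 100))
  expect_equal(r$mean_ribosomes, 0)
  expect_equal(r$production_rate, 0)
})

test_that("sparse regime: production rate approximately equals ir", {
  # needs ir << rate/footprint: the start is blocked ~footprint/rate time
  # units after each initiation, so production = 1/(1/ir + fp/rate); at
  # ir = 0.002 that correction is 2%
  cfg <- tasep_config(burn_in = 500, measure_time = 2e6, seed = 2)
  r <- simulate_single_mrna(rep(1, 100), ir = 0.002, cfg)
  expect_equal(r$production_rate, 0.002, tolerance = 0.05)
  # occupancy ~ ir * sum(1/rate) in the low-density limit
  expect_equal(r$mean_ribosomes, 0.002 * 100, tolerance = 0.1)
})

test_that("single-ribosome transit time is the sum of exponential means", {
  set.seed(51)
  rates <- runif(120, 0.5, 2)
  expected_transit <- sum(1 / rates)
  # with ir tiny, at most one ribosome is on the lattice; occupancy =
  # ir * transit, production = ir (renewal argument)
  cfg <- tasep_config(burn_in = 2000, measure_time = 6e5, seed = 3)
  r <- simulate_single_mrna(rates, ir = 0.001, cfg)
  transit_hat <- r$mean_ribosomes / r$production_rate
  expect_equal(transit_hat, expected_transit, tolerance = 0.05)
})

test_that("exclusion holds over a long run and occupancy respects packing", {
  cfg <- tasep_config(burn_in = 0, measure_time = 220000, seed = 4)
  r <- simulate_single_mrna(rep(1, 100), ir = 5, cfg, check_exclusion = TRUE)
  expect_gt(r$events, 1e6)
  expect_true(r$exclusion_ok)
  expect_lte(r$mean_ribosomes, floor(100 / 10))
})

test_that("whole-cell conservation is exact and responds to slow codons", {
  genome <- generate_genome(30, c(120L, 200L), seed = 52)
  rates <- setNames(rep(1, 61), sense_codons())
  copies <- setNames(rep(20L, 30), names(genome))
  ir <- setNames(rep(0.02, 30), names(genome))
  cell <- cell_state(genome, rates, copies, ir, total_ribosomes = 2000L,
                     total_mrnas = 600L)
  cfg <- tasep_config(burn_in = 100, measure_time = 300, seed = 5)
  r <- whole_cell_simulate(cell, cfg, check_exclusion = TRUE)
  expect_true(r$conservation_ok)
  expect_true(r$exclusion_ok)
  expect_gt(r$free_pool, 0)

  # all-zero initiation: the pool stays untouched
  cell0 <- cell_state(genome, rates, copies, setNames(rep(0, 30), names(genome)),
                      total_ribosomes = 2000L, total_mrnas = 600L)
  r0 <- whole_cell_simulate(cell0, cfg)
  expect_equal(r0$free_pool, 2000)

  # slowing every codon of a high-copy transcript sequesters ribosomes
  slow <- rates; slow[unique(genome[[1]])] <- 0.3
  cell_slow <- cell_state(genome, slow, copies, ir, total_ribosomes = 2000L,
                          total_mrnas = 600L)
  r_slow <- whole_cell_simulate(cell_slow, cfg)
  expect_lt(r_slow$free_pool, r$free_pool)
})

test_that("flux balance: initiation flux matches termination flux", {
  # at steady state production equals effective initiation; compare the
  # stochastic result with the low-density mean-field prediction
  rates <- rep(1, 150)
  cfg <- tasep_config(burn_in = 1000, measure_time = 60000, seed = 6)
  r <- simulate_single_mrna(rates, ir = 0.02, cfg)
  mf <- mean_field_single_mrna(rates, 0.02, footprint = 10)
  expect_equal(r$production_rate, mf$production_rate, tolerance = 0.1)
  expect_equal(r$mean_ribosomes, mf$mean_ribosomes, tolerance = 0.15)
})

test_that("cluster recoding preserves the protein and honours the weights", {
  genome <- generate_genome(6, c(60L, 90L), seed = 53)
  cluster <- names(genome)[1:3]
  w <- setNames(rep(1, 61), sense_codons())
  vs <- randomize_cluster_codons(genome, cluster, w, n_versions = 3, seed = 9)
  expect_length(vs, 3)
  for (v in vs) {
    for (g in cluster) {
      expect_equal(translate_codons(v[[g]]), translate_codons(genome[[g]]))
    }
    for (g in setdiff(names(genome), cluster)) {
      expect_identical(v[[g]], genome[[g]])
    }
  }
  # degenerate weights: one codon per family makes recoding deterministic
  fam <- synonymous_families()
  w0 <- setNames(rep(0, 61), sense_codons())
  for (cs in fam) w0[cs[1]] <- 1
  v0 <- randomize_cluster_codons(genome, cluster, w0, n_versions = 2, seed = 1)
  expect_identical(v0[[1]][cluster], v0[[2]][cluster])
  aa_of <- codon_to_aa()
  expect_identical(v0[[1]][[cluster[1]]],
                   unname(vapply(fam, `[[`, "", 1)[aa_of[genome[[cluster[1]]]]]))
  # uniform weights: per-family composition near uniform on a long gene
  long <- list(gL = rep(synonymous_families()$L, 400))
  vL <- randomize_cluster_codons(long, "gL", w, n_versions = 1, seed = 2)[[1]]
  tab <- table(factor(vL$gL, levels = synonymous_families()$L))
  p <- 1 / 6; n <- length(vL$gL)
  expect_true(all(abs(tab / n - p) < 3.5 * sqrt(p * (1 - p) / n)))
  expect_error(randomize_cluster_codons(genome, "nope", w), "absent")
})

test_that("translatome comparison implements the percent/z definitions", {
  orig <- list(free_pool = 100, mean_translation_rate = 10)
  rnd <- list(list(free_pool = 90, mean_translation_rate = 9),
              list(free_pool = 94, mean_translation_rate = 11))
  cmp <- compare_translatome(orig, rnd)
  expect_equal(cmp$pct_change_free_pool, -8)            # mean 92 vs 100
  expect_equal(cmp$z_free, (100 - 92) / sd(c(90, 94)))
  expect_equal(cmp$pct_change_mean_rate, 0)
  expect_warning(
    cmp0 <- compare_translatome(orig, list(list(free_pool = 90,
                                                mean_translation_rate = 10),
                                           list(free_pool = 92,
                                                mean_translation_rate = 10))),
    "zero variance")
  expect_true(is.na(cmp0$z_rate))
  # identical randomizations: zero percent change (both z's warn)
  same <- list(orig, orig)
  expect_warning(
    expect_warning(cmp_same <- compare_translatome(orig, same),
                   "zero variance"),
    "zero variance")
  expect_equal(cmp_same$pct_change_free_pool, 0)
})
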