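# Synthetic-data generator: determinism, composition, rate trajectories,
# profile statistics, PPI coupling.

test_that("genome generation is deterministic and respects constraints", {
  g1 <- generate_genome(20, c(50L, 80L), seed = 3)
  g2 <- generate_genome(20, c(50L, 80L), seed = 3)
  expect_identical(g1, g2)
  g3 <- generate_genome(20, c(50L, 80L), seed = 4)
  expect_false(identical(g1, g3))

  fixed <- generate_genome(10, c(45L, 45L), seed = 1)
  expect_true(all(lengths(fixed) == 45))
  expect_true(all(unlist(fixed) %in% sense_codons()))
  expect_error(generate_genome(5, c(30L, 60L)), ">= 45")

  dead <- setNames(rep(1, 61), sense_codons())
  dead[synonymous_families()$K] <- 0   # no codon left for lysine
  expect_error(generate_genome(5, codon_usage = dead), "K")
})

test_that("uniform codon usage converges to uniform frequencies", {
  g <- generate_genome(500, c(150L, 300L), seed = 11)
  tab <- table(factor(unlist(g), levels = sense_codons()))
  n <- sum(tab)
  p <- 1 / 61
  se <- sqrt(p * (1 - p) / n)
  # multinomial oracle: each frequency within 3 SE plus a small slack for
  # the 61 simultaneous comparisons
  expect_true(all(abs(tab / n - p) < 4 * se))
  expect_gt(mean(abs(tab / n - p) < 3 * se), 0.95)
})

test_that("rate trajectories honour noise, inversions and determinism", {
  base <- setNames(runif(61, 0.5, 2), sense_codons())
  flat <- generate_rate_trajectories(base, 4, noise_sd = 0, seed = 1)
  expect_equal(flat[, 1], flat[, 4])

  inv <- generate_rate_trajectories(
    base, 6, inversion = list(codons = c("CGG", "CCG"), timepoints = 5L),
    noise_sd = 0.05, seed = 2)
  expect_true(all(inv > 0))
  rk <- apply(inv, 2, rank)
  expect_true(all(rk[c("CGG", "CCG"), 5] > 0.9 * 61))
  expect_true(all(rk[c("CGG", "CCG"), -5] < 0.1 * 61 + 1))
  # rank at the designated time point exceeds the median rank elsewhere
  expect_true(all(rk[c("CGG", "CCG"), 5] >
                    apply(rk[c("CGG", "CCG"), -5], 1, median)))

  a <- generate_rate_trajectories(base, 4, noise_sd = 0.1, seed = 1)
  b <- generate_rate_trajectories(base, 4, noise_sd = 0.1, seed = 2)
  expect_false(identical(a, b))
})

test_that("simulated profiles track transcript level and dwell time", {
  genome <- generate_genome(30, c(60L, 120L), seed = 5)
  rates <- generate_rate_trajectories(setNames(rep(1, 61), sense_codons()),
                                      2, noise_sd = 0, seed = 1)
  lv <- generate_transcript_levels(names(genome), 2, seed = 2)
  lv[1, ] <- 0  # first gene silenced
  truth <- synthetic_truth(rates, lv, setNames(rep(0.1, 30), names(genome)),
                           pause_prob = 0, pause_scale = 1)
  p1 <- simulate_profiles(genome, truth, depth = 5, seed = 9)
  p2 <- simulate_profiles(genome, truth, depth = 5, seed = 9)
  expect_identical(p1, p2)

  zero_gene <- Filter(function(p) p$gene_id == names(genome)[1], p1)
  expect_true(all(vapply(zero_gene, function(p) sum(p$counts), 0) == 0))

  # mean count per codon is close to the requested depth
  all_counts <- unlist(lapply(p1, `[[`, "counts"))
  expect_equal(mean(all_counts), 5, tolerance = 0.15)

  truth2 <- synthetic_truth(rates, lv[-1, , drop = FALSE],
                            setNames(rep(0.1, 29), names(genome)[-1]))
  expect_error(simulate_profiles(genome, truth2, 5, 1), "absent from truth")
})

test_that("pause mixture produces an EMG-preferred NFC distribution", {
  # with a pause tail present, the EMG fit should beat a pure normal fit
  genome <- generate_genome(80, c(100L, 200L), seed = 6)
  rates <- generate_rate_trajectories(setNames(rep(1, 61), sense_codons()),
                                      2, noise_sd = 0, seed = 1)
  lv <- generate_transcript_levels(names(genome), 2, meanlog = 4, sdlog = 0.3,
                                   seed = 2)
  truth <- synthetic_truth(rates, lv, setNames(rep(0.1, 80), names(genome)),
                           pause_prob = 0.15, pause_scale = 1.5)
  profs <- simulate_profiles(genome, truth, depth = 40, seed = 3)
  stage1 <- profiles_to_samples(profs, genome)
  vals <- stage1$samples$t1$values
  expect_gt(length(vals), 0)
  x <- vals[[which.max(vapply(vals, length, 1L))]]
  expect_gt(length(x), 100)
  fit <- fit_emg(x)
  ll_norm <- sum(dnorm(x, mean(x), sd(x), log = TRUE))
  expect_gt(fit$loglik, ll_norm)
})

test_that("PPI generator couples edges to co-patterns and avoids self-edges", {
  set.seed(21)
  m <- matrix(rnorm(80 * 6), 80, 6,
              dimnames = list(sprintf("g%04d", 1:80), paste0("t", 1:6)))
  # impose two strong co-patterned blocks
  m[1:20, ] <- rep(sin(1:6), each = 20) + rnorm(120, 0, 0.1)
  m[21:40, ] <- rep(cos(1:6), each = 20) + rnorm(120, 0, 0.1)
  net1 <- generate_ppi_network(rownames(m), m, signal = 1, n_edges = 150,
                               seed = 4)
  expect_true(all(net1$confidence > 0 & net1$confidence <= 1))
  expect_true(all(net1$gene_a != net1$gene_b))
  co <- mtdr_coscore(m)
  edge_co <- co[cbind(match(net1$gene_a, rownames(co)),
                      match(net1$gene_b, rownames(co)))]
  all_co <- co[upper.tri(co)]
  expect_gt(median(edge_co), median(all_co, na.rm = TRUE))

  # signal = 0: edge co-scores look like random pairs (permutation oracle)
  net0 <- generate_ppi_network(rownames(m), m, signal = 0, n_edges = 150,
                               seed = 5)
  e0 <- co[cbind(match(net0$gene_a, rownames(co)),
                 match(net0$gene_b, rownames(co)))]
  expect_gt(wilcox.test(e0, all_co)$p.value, 0.01)
})
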