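# Codon indices, CV, demand, per-amino-acid TDR, equal-sample control.

test_that("tAI weights match a hand-computed toy family", {
  # alanine family GCT/GCC/GCA/GCG; anticodons AGC=2, GGC=1, TGC=0, CGC=0.
  # with all wobble constraints s = 0.5:
  #   W(GCT) = AGC + 0.5*GGC = 2.5 ; W(GCC) = GGC + 0.5*AGC = 2
  #   W(GCA) = TGC + 0.5*AGC = 1   ; W(GCG) = CGC + 0.5*TGC = 0 (fallback)
  tgcn <- c(AGC = 2, GGC = 1)
  s <- c(WC = 0, GU = 0.5, IC = 0.5, IA = 0.5, UG = 0.5)
  w <- compute_tai(tgcn, s)
  expect_equal(unname(w["GCT"]), 1.0)       # unique max W normalizes to 1
  expect_equal(unname(w["GCC"]), 2 / 2.5)
  expect_equal(unname(w["GCA"]), 1 / 2.5)
  expect_true("GCG" %in% attr(w, "fallback"))
  expect_true(all(w > 0 & w <= 1))

  # codons decodable only via wobble get W = 0 under s = 1 and fall back;
  # GCC keeps its Watson-Crick tRNA (GGC) and does not
  s1 <- c(WC = 0, GU = 1, IC = 1, IA = 1, UG = 1)
  w1 <- compute_tai(tgcn, s1)
  expect_true(all(c("GCA", "GCG") %in% attr(w1, "fallback")))
  expect_false("GCC" %in% attr(w1, "fallback"))
  expect_equal(unname(w1["GCC"]), 0.5)  # W = 1 vs max W = 2 (GCT)

  # invariance to rescaling all copy numbers
  expect_equal(as.numeric(compute_tai(tgcn * 10, s)), as.numeric(w))
  expect_error(compute_tai(c(AGC = 0)), "all-zero")
})

test_that("CAI groups take the per-family extremes and exclude Met/Trp", {
  set.seed(41)
  cai <- setNames(runif(61, 0.05, 1), sense_codons())
  gr <- select_cai_groups(cai)
  expect_length(gr$high, 18)
  expect_length(gr$low, 18)
  expect_false(any(c("ATG", "TGG") %in% c(gr$high, gr$low)))
  fam <- synonymous_families()[["L"]]  # 6-codon leucine family
  expect_equal(intersect(gr$high, fam), fam[which.max(cai[fam])])
  expect_equal(intersect(gr$low, fam), fam[which.min(cai[fam])])

  tie <- setNames(rep(0.5, 61), sense_codons())
  gr_tie <- select_cai_groups(tie)
  expect_gt(length(gr_tie$ties), 0)
  expect_length(gr_tie$high, 18)  # deterministic lexicographic tie-break
})

test_that("rank CV matches the direct formula and its invariances", {
  expect_equal(rank_cv(c(10, 20, 30)), 50)   # sd 10, mean 20
  expect_equal(rank_cv(c(7, 7, 7, 7)), 0)
  expect_equal(rank_cv(c(10, 20, 30) * 2), 50)  # scale invariance
  expect_error(rank_cv(5), ">= 2")
  # population-sd switch
  expect_equal(rank_cv(c(10, 20, 30), sd_type = "population"),
               100 * sqrt(2 / 3) * 10 / 20)
})

test_that("per-amino-acid TDR is the frequency-weighted family average", {
  tdr <- matrix(NA_real_, 61, 1, dimnames = list(sense_codons(), "t1"))
  freqs <- setNames(rep(0, 61), sense_codons())
  # single-codon amino acid: identity
  tdr["ATG", 1] <- 1.7; freqs["ATG"] <- 5
  # two-codon family with weights 0.75/0.25 and TDRs 2/4
  famK <- synonymous_families()$K
  tdr[famK, 1] <- c(2, 4); freqs[famK] <- c(75, 25)
  out <- amino_acid_tdr(tdr, freqs)
  expect_equal(out["M", "t1"], 1.7)
  expect_equal(out["K", "t1"], 2.5)
  expect_true(is.na(out["W", "t1"]))  # no fitted codon -> missing
  # uniform weights reduce to the arithmetic mean
  freqs[famK] <- c(1, 1)
  expect_equal(amino_acid_tdr(tdr, freqs)["K", "t1"], 3)
})

test_that("codon demand is transcript-weighted and family-normalized", {
  famK <- synonymous_families()$K   # AAA / AAG
  g <- list(g1 = c(rep(famK[1], 3), famK[2]))
  d <- codon_demand(g, c(g1 = 10))
  expect_equal(unname(d$demand[famK]), c(0.75, 0.25))

  # zero-RPKM gene contributes nothing
  g2 <- list(g1 = c(rep(famK[1], 3), famK[2]), g2 = rep(famK[2], 50))
  d2 <- codon_demand(g2, c(g1 = 10, g2 = 0))
  expect_equal(unname(d2$demand[famK]), c(0.75, 0.25))

  # brute-force oracle on a random toy genome
  set.seed(42)
  g3 <- generate_genome(5, c(50L, 60L), seed = 42)
  rpkm <- setNames(runif(5, 0, 20), names(g3))
  d3 <- codon_demand(g3, rpkm)
  brute <- setNames(rep(0, 61), sense_codons())
  for (gn in names(g3)) for (codon in g3[[gn]]) {
    brute[codon] <- brute[codon] + rpkm[gn]
  }
  expect_equal(d3$raw, brute)
  # per-family fractions sum to 1
  for (cs in synonymous_families()) {
    s <- sum(d3$demand[cs])
    if (!is.na(s)) expect_equal(s, 1, tolerance = 1e-9)
  }
})

test_that("demand ratios standardize against the vegetative time point", {
  d <- matrix(0.5, 61, 3, dimnames = list(sense_codons(), c("veg", "t1", "t2")))
  r <- demand_ratio(d, "veg")
  expect_true(all(r == 1))
  d2 <- d
  d2["AAA", "t1"] <- 1.0   # demand doubles at t1: raw ratio 0.5
  raw_ratio <- d2[, "veg"] / d2
  expect_equal(raw_ratio["AAA", "t1"], 0.5)
  r2 <- demand_ratio(d2, "veg")
  expect_equal(r2["AAA", "t1"], 0.5 / mean(c(1, 0.5, 1)))
  expect_error(demand_ratio(d, "nope"), "not in demand")
})

test_that("equal-sample control resizes to max(100, min n) deterministically", {
  set.seed(43)
  samples <- list(values = list(AAA = rnorm(250, 1), GAA = rnorm(400, 1),
                                TTG = rnorm(320, 1)),
                  n = c(AAA = 250L, GAA = 400L, TTG = 320L),
                  excluded = character(0))
  ctl <- equal_sample_control(samples, seed = 7)
  expect_true(all(vapply(ctl$values, length, 1L) == 250))
  expect_equal(ctl$common_size, 250)
  # subsample is a subset of the original values
  expect_true(all(ctl$values$GAA %in% samples$values$GAA))
  ctl2 <- equal_sample_control(samples, seed = 7)
  expect_identical(ctl$values, ctl2$values)
  # equal sizes: only a permutation
  eq <- list(values = list(AAA = rnorm(120), GAA = rnorm(120)),
             n = c(AAA = 120L, GAA = 120L), excluded = character(0))
  ctleq <- equal_sample_control(eq, seed = 1)
  expect_setequal(ctleq$values$AAA, eq$values$AAA)
})

test_that("CV group test is one-sided with the expected symmetry", {
  set.seed(44)
  cv <- setNames(runif(61, 20, 80), sense_codons())
  lo <- sense_codons()[1:15]; hi <- sense_codons()[20:34]
  # same distribution: p around 0.5
  r <- cv_group_test(cv, lo, hi)
  expect_gt(r$p, 0.05)
  # strong shift: low group much larger -> small p
  cv2 <- cv; cv2[lo] <- cv2[lo] + 100
  expect_lt(cv_group_test(cv2, lo, hi)$p, 1e-4)
  # swapping the groups flips the one-sided direction
  r_fwd <- cv_group_test(cv2, lo, hi)
  r_rev <- cv_group_test(cv2, hi, lo)
  expect_equal(r_fwd$p + r_rev$p, 1, tolerance = 0.01)
  expect_error(cv_group_test(cv, lo, lo), "overlap")
})
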