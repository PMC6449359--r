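# Profile IO, trimming, coverage filtering, NFC normalization, collection.

test_that("profile TSV round trip and validation", {
  p <- write_profile_tsv(c("gA\tt1\t1,2,3", "gB\tt1\t0,0,5", "gA\tt2\t4,4,4"))
  prof <- read_profiles(p)
  expect_length(prof, 3)
  expect_identical(prof[[2]]$counts, c(0L, 0L, 5L))

  bad <- write_profile_tsv(c("gA\tt1\t1,2,3", "gB\tt1\t1,-1,2"))
  expect_error(read_profiles(bad), "line 3.*-1")
  frac <- write_profile_tsv("gA\tt1\t1,2.5,3")
  expect_error(read_profiles(frac), "2.5")

  empty <- write_profile_tsv(character(0))
  expect_warning(res <- read_profiles(empty), "empty")
  expect_length(res, 0)

  # writer inverts the reader
  out <- tempfile(fileext = ".tsv")
  write_profiles(prof, out)
  expect_equal(read_profiles(out), prof)
})

test_that("trimming masks 20 codons at each end and computes coverage", {
  p <- trim_and_coverage(make_profile(rep(1L, 100)))
  expect_length(p$window, 60)          # 100 - 2*20 positions remain
  expect_identical(p$window, 21:80)
  expect_equal(p$coverage, 1.0)

  zeros <- trim_and_coverage(make_profile(rep(0L, 100)))
  expect_equal(zeros$coverage, 0.0)

  mixed <- make_profile(c(rep(9L, 20), rep(c(1L, 0L), 30), rep(9L, 20)))
  expect_equal(trim_and_coverage(mixed)$coverage, 0.5)

  short <- trim_and_coverage(make_profile(rep(1L, 40)))
  expect_false(short$usable)
})

test_that("reference-set coverage threshold is inclusive at 40%", {
  counts_for_cov <- function(cov) {
    # 140-codon gene: 100 unmasked positions, cov*100 of them covered
    c(rep(0L, 20), rep(1L, round(cov * 100)), rep(0L, 100 - round(cov * 100)),
      rep(0L, 20))
  }
  p39 <- trim_and_coverage(make_profile(counts_for_cov(0.39), "g39"))
  p40 <- trim_and_coverage(make_profile(counts_for_cov(0.40), "g40"))
  expect_equal(p39$coverage, 0.39)
  expect_equal(p40$coverage, 0.40)
  kept <- build_reference_set(list(p39, p40))
  expect_identical(vapply(kept, `[[`, "", "gene_id"), "g40")
  # threshold 0 keeps everything usable
  expect_length(build_reference_set(list(p39, p40), min_coverage = 0), 2)
  expect_error(build_reference_set(list(p40), min_coverage = 1.5), "0, 1")
})

test_that("NFC normalization divides by the zero-excluded average count", {
  p <- trim_and_coverage(make_profile(c(2L, 4L, 6L)), n_trim = 0)
  n <- normalize_to_nfc(p)
  expect_equal(unname(n$nfc), c(0.5, 1.0, 1.5))
  expect_equal(mean(n$nfc, na.rm = TRUE), 1)

  const <- normalize_to_nfc(trim_and_coverage(make_profile(c(5L, 5L, 5L)),
                                              n_trim = 0))
  expect_equal(unname(const$nfc), c(1, 1, 1))

  # zero positions excluded from the average and from the output
  z <- normalize_to_nfc(trim_and_coverage(make_profile(c(0L, 4L, 8L)),
                                          n_trim = 0))
  expect_equal(unname(z$nfc), c(NA, 4 / 6, 8 / 6))

  # include_zeros switch: average over all unmasked positions
  z2 <- normalize_to_nfc(trim_and_coverage(make_profile(c(0L, 4L, 8L)),
                                           n_trim = 0), include_zeros = TRUE)
  expect_equal(unname(z2$nfc), c(0, 1, 2))

  expect_warning(
    expect_null(normalize_to_nfc(trim_and_coverage(make_profile(c(0L, 0L)),
                                                   n_trim = 0))),
    "all-zero")
})

test_that("normalization is invariant to scaling the counts", {
  set.seed(5)
  counts <- rpois(80, 3)
  a <- normalize_to_nfc(trim_and_coverage(make_profile(counts), n_trim = 10))
  b <- normalize_to_nfc(trim_and_coverage(make_profile(counts * 7L), n_trim = 10))
  expect_equal(a$nfc, b$nfc)
})

test_that("per-codon collection counts occurrences exactly and applies min_n", {
  genome <- tiny_genome()
  profs <- list(
    trim_and_coverage(make_profile(rep(1L, 60), "gA"), n_trim = 5),
    trim_and_coverage(make_profile(rep(2L, 50), "gB"), n_trim = 5)
  )
  nfc <- lapply(profs, normalize_to_nfc)
  samples <- collect_codon_nfc(nfc, genome, min_n = 1)
  s <- samples$t1
  # counting oracle: occurrences of each codon inside the windows
  expected <- table(c(genome$gA[6:55], genome$gB[6:45]))
  expect_equal(s$n[names(expected)], c(expected)[names(expected)],
               ignore_attr = TRUE)
  # sum of sample sizes = covered unmasked positions of the reference set
  expect_equal(sum(s$n), 50 + 40)

  # admission threshold: a codon with n = 99 is excluded at min_n = 100
  big <- collect_codon_nfc(nfc, genome, min_n = 100)$t1
  expect_true(all(vapply(big$values, length, 1L) >= 100))
  under <- names(s$n)[s$n < 100 & s$n > 0]
  expect_true(all(under %in% big$excluded))

  # length mismatch is an error naming the gene
  bad_genome <- genome
  bad_genome$gA <- genome$gA[1:59]
  expect_error(collect_codon_nfc(nfc, bad_genome), "gA")
})
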