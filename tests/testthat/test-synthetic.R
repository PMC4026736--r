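# Synthetic cohort generator: determinism, truth consistency, frequency
# calibration, chip masking, Balding-Nichols moments, X-marker structure.

spec1 <- function(n = 100L)
  population_spec("Caucasian", default_star_freqs("Total"), n)

test_that("panel generation is deterministic and respects degenerate freqs", {
  ps <- population_spec("Caucasian", c("*1" = 1), 50L)
  p1 <- build_locus_panel(ps, 50, n_flank = 4, seed = 11)
  p2 <- build_locus_panel(ps, 50, n_flank = 4, seed = 11)
  expect_identical(p1, p2)
  expect_true(all(p1$haplotypes[, "rs1800460"] == 0L))
  expect_true(all(p1$haplotypes[, "rs1142345"] == 0L))
  p3 <- build_locus_panel(ps, 50, n_flank = 4, seed = 12)
  expect_false(identical(p1$haplotypes, p3$haplotypes))
})

test_that("invalid population frequencies are rejected", {
  expect_error(population_spec("Caucasian", c("*1" = 0.5, "*3A" = 0.6), 10L),
               "sum to 1")
  expect_error(population_spec("Caucasian", c("*1" = 0.5, "*9" = 0.5), 10L),
               "named")
  expect_error(build_locus_panel(spec1(), n_haps_per_pop = 1), ">= 2")
  expect_error(tpmt_variants(-1), ">= 0")
})

test_that("realized *3A haplotype fraction is within 4 binomial SE", {
  # pooled cohort frequencies, 20,000 haplotypes
  f3a <- default_star_freqs("Total")[["*3A"]]
  p <- build_locus_panel(spec1(), n_haps_per_pop = 20000, n_flank = 2,
                         seed = 21)
  cores <- haplotype_to_star(p$haplotypes[, "rs1800460"],
                             p$haplotypes[, "rs1142345"])
  se <- sqrt(f3a * (1 - f3a) / 20000)
  expect_lt(abs(mean(cores == "*3A") - f3a), 4 * se)
})

test_that("cohort truth is consistent with the drawn haplotypes", {
  ps <- spec1(200L)
  panel <- build_locus_panel(ps, 400, n_flank = 6, seed = 31)
  ch <- simulate_cohort(panel, ps, genotyping_error_rate = 0.02,
                        switch_error_rate = 0.02, seed = 32)
  hA <- ch$truth_haplotypes$hapA; hB <- ch$truth_haplotypes$hapB
  redip <- star_diplotype(
    haplotype_to_star(hA[, "rs1800460"], hA[, "rs1142345"]),
    haplotype_to_star(hB[, "rs1800460"], hB[, "rs1142345"]))
  expect_identical(redip, ch$truth$diplotype)
})

test_that("noiseless typed data equals truth at probed markers only", {
  ps <- spec1(150L)
  panel <- build_locus_panel(ps, 300, n_flank = 6, seed = 41)
  ch <- simulate_cohort(panel, ps, seed = 42)
  for (chip in names(ch$typed)) {
    td <- ch$typed[[chip]]
    rows <- match(td$sample_ids, ch$truth$sample_id)
    probed <- td$probed_ids
    expect_identical(td$hapA[, probed],
                     ch$truth_haplotypes$hapA[rows, probed])
    unprobed <- setdiff(colnames(td$hapA), probed)
    expect_true(all(is.na(td$hapA[, unprobed])))
  }
  # the 550-like design probes neither causal SNP
  expect_false(any(c("rs1800460", "rs1142345") %in%
                     ch$typed[["550-like"]]$probed_ids))
  # the quad-like design probes rs1800460 but not rs1142345
  expect_true("rs1800460" %in% ch$typed[["quad-like"]]$probed_ids)
  expect_false("rs1142345" %in% ch$typed[["quad-like"]]$probed_ids)
})

test_that("random mating reproduces the Hardy-Weinberg *1/*1 expectation", {
  ps <- spec1(20000L)
  panel <- build_locus_panel(ps, 20000, n_flank = 2, seed = 51)
  ch <- simulate_cohort(panel, ps, seed = 52)
  f1 <- default_star_freqs("Total")[["*1"]]
  exp_11 <- f1^2 * 20000
  sd_11 <- sqrt(20000 * f1^2 * (1 - f1^2))
  obs_11 <- sum(ch$truth$diplotype == "*1/*1")
  # 4 SD plus slack for the panel's own frequency sampling noise
  expect_lt(abs(obs_11 - exp_11), 6 * sd_11)
})

test_that("Balding-Nichols frequencies have the stated first two moments", {
  ps <- list(population_spec("Caucasian", c("*1" = 1), 10L),
             population_spec("African", c("*1" = 1), 10L))
  # fst = 0: population frequencies equal the ancestral frequency exactly
  a0 <- simulate_ancestry_markers(200, ps, fst = 0, seed = 61)
  expect_equal(a0$pop_freqs[1, ], a0$pop_freqs[2, ])
  # fst = 0.1, p = 0.5: Var = p(1-p)F = 0.025, tolerance 20%
  a1 <- simulate_ancestry_markers(5000, ps, fst = 0.1,
                                  ancestral_freq_fn = function(n) rep(0.5, n),
                                  seed = 62)
  v <- mean(apply(a1$pop_freqs, 1, stats::var))
  expect_lt(abs(v - 0.025), 0.2 * 0.025)
  expect_lt(abs(mean(a1$pop_freqs) - 0.5), 0.01)
  expect_error(simulate_ancestry_markers(100, ps, fst = 1), "fst")
  expect_error(simulate_ancestry_markers(0, ps), "n_markers")
})

test_that("X markers: males are never heterozygous before error", {
  sex <- rep(c("male", "female"), each = 40)
  g <- simulate_x_markers(1000, sex, maf_fn = function(n) rep(0.5, n),
                          seed = 71)
  het <- rowMeans(g == 1L)
  expect_true(all(het[1:40] == 0))
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_true(all(abs(het[41:80] - 0.5) < 4 * se + 0.05))
  # single-allele miscall model: male heterozygosity ~= error rate
  ge <- simulate_x_markers(20000, "male", maf_fn = function(n) rep(0.3, n),
                           error_rate = 0.01, seed = 72)
  expect_lt(abs(mean(ge == 1L) - 0.01), 0.004)
})

test_that("cohort simulation is deterministic under a fixed seed", {
  ps <- spec1(60L)
  panel <- build_locus_panel(ps, 100, seed = 81)
  c1 <- simulate_cohort(panel, ps, genotyping_error_rate = 0.01, seed = 82)
  c2 <- simulate_cohort(panel, ps, genotyping_error_rate = 0.01, seed = 82)
  expect_identical(c1, c2)
})
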