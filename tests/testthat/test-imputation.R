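# Haplotype-copying HMM, genotype posteriors, info score and hard calls.

two_hap_panel <- function() {
  structure(list(
    variants = data.frame(id = c("m1", "m2"), chrom = "6",
                          pos = c(100L, 200L), ref = "A", alt = "G",
                          stringsAsFactors = FALSE),
    haplotypes = matrix(c(0L, 1L, 0L, 1L), 2,
                        dimnames = list(NULL, c("m1", "m2"))),
    hap_population = c("p", "p")), class = "haplotype_panel")
}

test_that("2-state forward-backward reproduces the hand computation", {
  # panel {(0,0), (1,1)}, observed 0 at m1, eps = 0.01, switch prob 0.05
  # (rho = 0.1, K = 2): gamma(m1) = (0.99, 0.01), so
  # P(state 2 at m2) = 0.99 * 0.05 + 0.01 * 0.95 = 0.059
  p <- impute_haplotype(c(m1 = 0), two_hap_panel(),
                        imputation_params(rho = 0.1, eps = 0.01))
  expect_equal(p[["m2"]], 0.059, tolerance = 1e-9)
  expect_equal(p[["m1"]], 0.01, tolerance = 1e-9)
})

test_that("posteriors at typed markers concentrate as eps shrinks", {
  prev <- Inf
  for (eps in c(0.1, 0.01, 0.001, 1e-4)) {
    p <- impute_haplotype(c(m1 = 0), two_hap_panel(),
                          imputation_params(rho = 0.1, eps = eps))
    expect_lt(p[["m1"]], prev)
    prev <- p[["m1"]]
  }
  expect_lt(prev, 1e-3)
})

test_that("a target identical to a panel haplotype copies its alleles", {
  set.seed(11)
  vids <- c(sprintf("t%02d", 1:10), "untyped")
  H <- matrix(rbinom(20 * 11, 1, 0.5), 20, dimnames = list(NULL, vids))
  typed_ids <- vids[1:10]
  # ensure haplotype 7 is the unique panel match at the typed markers
  stopifnot(sum(apply(H[, typed_ids], 1,
                      function(h) all(h == H[7, typed_ids]))) == 1)
  panel <- structure(list(
    variants = data.frame(id = vids, chrom = "6", pos = seq_along(vids),
                          ref = "A", alt = "G", stringsAsFactors = FALSE),
    haplotypes = H, hap_population = rep("p", 20)),
    class = "haplotype_panel")
  p <- impute_haplotype(H[7, typed_ids], panel,
                        imputation_params(rho = 1e-3, eps = 1e-4))
  expect_lt(abs(p[["untyped"]] - H[7, "untyped"]), 0.01)
})

test_that("with no typed markers the posterior is the panel frequency", {
  ps <- population_spec("Caucasian", default_star_freqs("Total"), 10L)
  panel <- build_locus_panel(ps, 200, n_flank = 4, seed = 12)
  eps <- 0.001
  p <- impute_haplotype(stats::setNames(numeric(0), character(0)), panel,
                        imputation_params(eps = eps))
  f <- colMeans(panel$haplotypes)
  expect_true(all(abs(p - f) <= 2 * eps))
})

test_that("invalid imputation inputs are rejected", {
  expect_error(impute_haplotype(c(zz = 0), two_hap_panel()), "absent")
  empty <- two_hap_panel()
  empty$haplotypes <- empty$haplotypes[0, , drop = FALSE]
  expect_error(impute_haplotype(c(m1 = 0), empty), "empty")
  expect_error(imputation_params(rho = 1), "rho")
  expect_error(imputation_params(eps = 0.5), "eps")
})

test_that("genotype posteriors combine haplotypes under independence", {
  expect_equal(unname(genotype_posteriors(1, 1)[1, ]), c(0, 0, 1))
  expect_equal(unname(genotype_posteriors(0.5, 0.5)[1, ]),
               c(0.25, 0.5, 0.25))
  set.seed(13)
  a <- runif(100); b <- runif(100)
  gp <- genotype_posteriors(a, b)
  expect_equal(rowSums(gp), rep(1, 100), tolerance = 1e-12)
  expect_error(genotype_posteriors(1.2, 0), "0,1")
})

test_that("info score matches hand computation and conventions", {
  s <- info_score(rbind(c(0.25, 0.5, 0.25), c(1, 0, 0)))
  expect_equal(s$info, 1 / 3, tolerance = 1e-9)
  expect_equal(s$theta, 0.25)
  # degenerate posteriors -> no variance -> info 1
  expect_equal(info_score(rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)))$info, 1)
  # theta = 0 -> info 1 by convention
  expect_equal(info_score(rbind(c(1, 0, 0), c(1, 0, 0)))$info, 1)
  expect_error(info_score(matrix(numeric(0), 0, 3)), "empty")
})

test_that("info equals 1 - mean dosage variance over 2 theta (1 - theta)", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    raw <- matrix(rexp(3 * n), n)
    probs <- raw / rowSums(raw)
    e <- probs %*% c(0, 1, 2)
    # brute-force per-sample dosage variance from the genotype distribution
    v <- rowSums(probs * (matrix(c(0, 1, 2), n, 3, byrow = TRUE) -
                            matrix(e, n, 3))^2)
    theta <- sum(e) / (2 * n)
    expected <- 1 - mean(v) / (2 * theta * (1 - theta))
    expect_equal(info_score(probs)$info, min(1, max(0, expected)),
                 tolerance = 1e-9)
  }
})

test_that("info filtering is inclusive at the threshold", {
  infos <- data.frame(variant_id = c("a", "b", "c"),
                      info = c(0.95, 0.89, 0.90))
  expect_identical(filter_variants(infos, 0.9), c("a", "c"))
  expect_error(filter_variants(infos, 1.2), "threshold")
})

test_that("hard calls respect the threshold and the tie rule", {
  expect_identical(best_guess_genotype(c(0.95, 0.04, 0.01)), 0L)
  expect_true(is.na(best_guess_genotype(c(0.5, 0.4, 0.1), 0.9)))
  expect_true(is.na(best_guess_genotype(c(0.5, 0.5, 0), 0.5)))
  expect_identical(best_guess_genotype(rbind(c(0, 0.05, 0.95),
                                             c(0.1, 0.9, 0)), 0.9),
                   c(2L, 1L))
})

test_that("genotype posteriors from the HMM are normalized everywhere", {
  ps <- population_spec("Caucasian", default_star_freqs("Total"), 40L)
  panel <- build_locus_panel(ps, 100, n_flank = 6, seed = 15)
  ch <- simulate_cohort(panel, ps, seed = 16)
  im <- impute_chip(ch$typed[["550-like"]], panel)
  tot <- im$posteriors$p0 + im$posteriors$p1 + im$posteriors$p2
  expect_true(all(abs(tot - 1) < 1e-9))
  expect_true(all(im$posteriors$p0 >= -1e-12))
  expect_true(all(im$dosage >= 0 & im$dosage <= 2))
})
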