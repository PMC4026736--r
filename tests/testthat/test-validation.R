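# Confusion matrices, concordance, validation-set merging and one-vs-rest
# diagnostic metrics, anchored on the shipped validation tables.

test_that("pairs reconstruct the genotyping confusion matrix", {
  fx <- tpmt_fixtures()
  t5 <- fx$table5_genotyping
  pairs <- pairs_from_confusion(t5, "genotyping")
  expect_identical(nrow(pairs), 583L)
  m <- confusion_matrix(pairs, rownames(t5))
  expect_equal(unclass(m), unclass(t5), ignore_attr = TRUE)
  expect_identical(unname(diag(as.matrix(m))), c(553L, 26L, 3L))
  expect_identical(m["*1/*3C", "*1/*1"], 1L)
  expect_error(confusion_matrix(pairs, c("*1/*1", "*1/*3A")), "outside")
})

test_that("all-agreeing and empty inputs give diagonal and zero matrices", {
  p <- validation_pairs(1:5, rep("a", 5), rep("a", 5))
  m <- confusion_matrix(p, c("a", "b"))
  expect_identical(unname(unclass(m)), rbind(c(5L, 0L), c(0L, 0L)))
  m0 <- confusion_matrix(p[0, ], c("a", "b"))
  expect_true(all(m0 == 0L))
  expect_error(concordance_percent(m0), "empty")
})

test_that("concordance matches the published values", {
  fx <- tpmt_fixtures()
  expect_equal(concordance_percent(fx$table5_genotyping), 100 * 582 / 583)
  expect_equal(round(concordance_percent(fx$table5_genotyping), 1), 99.8)
  expect_equal(concordance_percent(fx$table6_sequencing), 100 * 50 / 59)
  expect_equal(round(concordance_percent(fx$table6_sequencing), 1), 84.7)
  expect_equal(concordance_percent(diag(3)), 100)
})

test_that("collapsing to defective-allele counts maps labels correctly", {
  p <- validation_pairs("x", "*1/*3A", "*3A/*3A")
  cp <- collapse_to_defective_count(p)
  expect_identical(cp$imputed, "1")
  expect_identical(cp$observed, "2")
  p2 <- validation_pairs("y", "*3B/*3C", "*3B/*3C")
  expect_identical(unlist(collapse_to_defective_count(p2)[, 2:3],
                          use.names = FALSE), c("2", "2"))
  # sequencing-table pairs collapse to observed marginals (1, 33, 25)
  fx <- tpmt_fixtures()
  cp6 <- collapse_to_defective_count(
    pairs_from_confusion(fx$table6_sequencing, "sequencing"))
  m6 <- confusion_matrix(cp6, c("0", "1", "2"))
  expect_equal(unname(colSums(m6)), c(1, 33, 25))
  expect_error(collapse_to_defective_count(
    validation_pairs("z", NA_character_, "*1/*1")), "no-call")
})

test_that("merging the two validation sets yields 630 unique pairs", {
  vp <- fixture_validation_pairs()
  expect_identical(nrow(vp$genotyping), 583L)
  expect_identical(nrow(vp$sequencing), 59L)
  expect_identical(nrow(vp$merged), 630L)
  expect_identical(anyDuplicated(vp$merged$sample_id), 0L)
  # overlap samples keep the sequencing record
  ov <- grep("OVERLAP", vp$merged$sample_id)
  expect_identical(unique(vp$merged$source[ov]), "sequencing")
  # no overlap -> simple concatenation
  a <- validation_pairs("a1", "*1/*1", "*1/*1")
  b <- validation_pairs("b1", "*1/*3A", "*1/*3A", "sequencing")
  expect_identical(nrow(merge_validation_sets(a, b)), 2L)
  # conflicting labels for an overlapping sample -> error naming it
  b2 <- validation_pairs("a1", "*1/*3C", "*1/*1", "sequencing")
  expect_error(merge_validation_sets(a, b2), "a1")
})

test_that("the merged set collapses to the published defective-count matrix", {
  fx <- tpmt_fixtures()
  vp <- fixture_validation_pairs(fx)
  m <- confusion_matrix(collapse_to_defective_count(vp$merged),
                        c("0", "1", "2"))
  expect_equal(unclass(m), unclass(fx$table7_defective),
               ignore_attr = TRUE)
  expect_equal(concordance_percent(m), 100 * (553 + 45 + 25) / 630)
})

test_that("one-vs-rest metrics reproduce the published 12 cells", {
  fx <- tpmt_fixtures()
  m <- fx$table7_defective
  printed <- list(
    "0" = c(sensitivity = 99.64, specificity = 100, ppv = 100, npv = 97.40),
    "1" = c(sensitivity = 90.00, specificity = 99.83, ppv = 97.82,
            npv = 99.14),
    "2" = c(sensitivity = 100, specificity = 99.01, ppv = 80.64, npv = 100))
  for (cl in names(printed)) {
    got <- one_vs_rest_metrics(m, cl)
    for (metric in names(printed[[cl]]))
      expect_equal(got[[metric]], printed[[cl]][[metric]], tolerance = 0.011,
                   label = paste(cl, metric))
  }
  g1 <- one_vs_rest_metrics(m, "1")
  expect_identical(c(g1$TP, g1$FP, g1$FN, g1$TN), c(45L, 1L, 5L, 579L))
})

test_that("metrics agree with a brute-force tally on random matrices", {
  set.seed(31)
  brute <- function(pairs, cl) {
    tp <- sum(pairs$imputed == cl & pairs$observed == cl)
    fp <- sum(pairs$imputed == cl & pairs$observed != cl)
    fn <- sum(pairs$imputed != cl & pairs$observed == cl)
    tn <- sum(pairs$imputed != cl & pairs$observed != cl)
    c(tp, fp, fn, tn)
  }
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    classes <- letters[1:k]
    m <- matrix(rpois(k * k, 3), k, dimnames = list(classes, classes))
    pairs <- pairs_from_confusion(m)
    for (cl in classes) {
      got <- one_vs_rest_metrics(m, cl)
      expect_identical(c(got$TP, got$FP, got$FN, got$TN), brute(pairs, cl))
      expect_identical(got$TP + got$FP + got$FN + got$TN, sum(m))
    }
  }
})

test_that("zero denominators yield flagged NAs, never silent zeros", {
  m <- matrix(c(5L, 0L, 0L, 0L), 2, dimnames = list(c("a", "b"), c("a", "b")))
  got <- one_vs_rest_metrics(m, "b")
  expect_true(is.na(got$sensitivity))  # no observed b at all
  expect_true(is.na(got$ppv))          # never imputed b
  expect_true(all(c("sensitivity", "ppv") %in% got$undefined))
  expect_equal(got$specificity, 100)
})
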