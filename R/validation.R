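# Validation of imputed calls against gold-standard genotypes: confusion
# matrices, overall concordance, one-vs-rest sensitivity / specificity /
# PPV / NPV, merging of genotyping and sequencing validation sets, and
# collapsing of diplotypes to defective-allele counts.

#' Build validation pairs
#'
#' @param sample_id Identifiers (unique within a source).
#' @param imputed,observed Class labels.
#' @param source `"genotyping"` or `"sequencing"`.
#' @return data.frame of validation pairs.
#' @export
validation_pairs <- function(sample_id, imputed, observed,
                             source = "genotyping") {
  source <- match.arg(source, c("genotyping", "sequencing"))
  data.frame(sample_id = sample_id, imputed = imputed, observed = observed,
             source = source, stringsAsFactors = FALSE)
}

#' Imputed-vs-observed confusion matrix
#'
#' Rows are imputed classes, columns observed classes, in the given order.
#'
#' @param pairs A [validation_pairs()] data.frame.
#' @param classes Class order; every label in `pairs` must be included.
#' @return A `tpmt_confusion` integer matrix.
#' @export
confusion_matrix <- function(pairs, classes) {
  bad <- setdiff(unique(c(pairs$imputed, pairs$observed)), classes)
  if (length(bad)) stop("label outside class order: ",
                        paste(bad, collapse = ", "))
  m <- table(factor(pairs$imputed, levels = classes),
             factor(pairs$observed, levels = classes))
  m <- as.matrix(unclass(m))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(imputed = classes, observed = classes)
  structure(m, class = c("tpmt_confusion", class(m)))
}

#' @export
print.tpmt_confusion <- function(x, ...) {
  cat(sprintf("confusion matrix (%d pairs), concordance %.2f%%\n",
              sum(x), concordance_percent(x)))
  print(unclass(x))
  invisible(x)
}

#' Overall concordance of a confusion matrix
#'
#' @param m Square confusion matrix with a positive total.
#' @return Percent: 100 x trace / total.
#' @export
concordance_percent <- function(m) {
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(as.matrix(m))) / total
}

#' Collapse diplotype-resolution pairs to defective-allele counts
#'
#' Maps each diplotype label to its number of defective alleles, giving
#' classes `"0"`, `"1"`, `"2"`.  No-call labels are rejected.
#'
#' @param pairs Validation pairs with diplotype labels.
#' @return Pairs over the three count classes.
#' @export
collapse_to_defective_count <- function(pairs) {
  if (anyNA(pairs$imputed) || anyNA(pairs$observed))
    stop("no-call labels cannot be collapsed")
  pairs$imputed <- as.character(defective_count(pairs$imputed))
  pairs$observed <- as.character(defective_count(pairs$observed))
  pairs
}

#' Merge genotyping and sequencing validation sets
#'
#' Samples present in both sources are counted once; the sequencing record
#' (the stronger gold standard) is kept.  Overlapping samples must carry
#' identical imputed and observed labels in both sources; conflicts raise
#' an error listing the offending samples.
#'
#' @param primary Genotyping pairs.
#' @param secondary Sequencing pairs.
#' @return Deduplicated pairs, `nrow = |primary| + |secondary| - |overlap|`.
#' @export
merge_validation_sets <- function(primary, secondary) {
  overlap <- intersect(primary$sample_id, secondary$sample_id)
  if (length(overlap)) {
    a <- primary[match(overlap, primary$sample_id), ]
    b <- secondary[match(overlap, secondary$sample_id), ]
    bad <- overlap[a$imputed != b$imputed | a$observed != b$observed]
    if (length(bad))
      stop("conflicting labels for overlapping samples: ",
           paste(bad, collapse = ", "))
  }
  rbind(primary[!primary$sample_id %in% overlap, ], secondary)
}

#' One-vs-rest diagnostic metrics for one class
#'
#' TP is the diagonal cell of the class; FP its remaining row mass
#' (called the class but observed otherwise); FN its remaining column
#' mass; TN everything else.  Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN), all as percents.
#' A zero denominator yields NA for that metric (flagged, never silently
#' 0).
#'
#' @param m Confusion matrix (imputed rows x observed columns).
#' @param class Class label present in `m`.
#' @return List: class, TP, FP, FN, TN, sensitivity, specificity, ppv,
#'   npv, undefined (names of metrics with zero denominators).
#' @export
one_vs_rest_metrics <- function(m, class) {
  m <- as.matrix(m)
  if (!class %in% rownames(m)) stop("class not in matrix")
  tp <- m[class, class]
  fp <- sum(m[class, ]) - tp
  fn <- sum(m[, class]) - tp
  tn <- sum(m) - tp - fp - fn
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- list(class = class, TP = tp, FP = fp, FN = fn, TN = tn,
              sensitivity = pct(tp, tp + fn),
              specificity = pct(tn, tn + fp),
              ppv = pct(tp, tp + fp),
              npv = pct(tn, tn + fn))
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv")], is.na, logical(1))))
  out
}

#' One-vs-rest metrics for every class of a confusion matrix
#'
#' @param m Confusion matrix.
#' @return data.frame, one row per class, with counts and percent metrics.
#' @export
all_metrics <- function(m) {
  do.call(rbind, lapply(rownames(as.matrix(m)), function(cl) {
    x <- one_vs_rest_metrics(m, cl)
    data.frame(class = cl, TP = x$TP, FP = x$FP, FN = x$FN, TN = x$TN,
               sensitivity = x$sensitivity, specificity = x$specificity,
               ppv = x$ppv, npv = x$npv, stringsAsFactors = FALSE)
  }))
}

#' Expand a confusion matrix into validation pairs
#'
#' Inverse of [confusion_matrix()] up to sample identity; used to rebuild
#' per-sample pairs from published count matrices.
#'
#' @param m Confusion matrix (imputed rows x observed columns).
#' @param source Pair source tag.
#' @param id_prefix Prefix for generated sample ids.
#' @return Validation pairs with `sum(m)` rows.
#' @export
pairs_from_confusion <- function(m, source = "genotyping",
                                 id_prefix = "V") {
  m <- as.matrix(m)
  imputed <- rep(rep(rownames(m), ncol(m)), as.vector(m))
  observed <- rep(rep(colnames(m), each = nrow(m)), as.vector(m))
  validation_pairs(sprintf("%s%04d", id_prefix, seq_along(imputed)),
                   imputed, observed, source)
}

#' Rebuild the published validation sets as per-sample pairs
#'
#' Reconstructs the 583 genotyping and 59 sequencing validation pairs from
#' the shipped confusion matrices, marking 12 samples as present in both
#' sets (drawn from the imputed `*1/*3A` / observed `*1/*3A` cell of each,
#' the only cell large enough in both, with consistent labels as the study
#' reports).  Merging then yields 630 unique pairs.
#'
#' @param fixtures Output of [tpmt_fixtures()].
#' @return List: `genotyping`, `sequencing` (pair data.frames),
#'   `merged` (630 deduplicated pairs).
#' @export
fixture_validation_pairs <- function(fixtures = tpmt_fixtures()) {
  geno <- pairs_from_confusion(fixtures$table5_genotyping, "genotyping", "G")
  seq_ <- pairs_from_confusion(fixtures$table6_sequencing, "sequencing", "Q")
  shared_ids <- sprintf("OVERLAP%02d", 1:12)
  g_idx <- which(geno$imputed == "*1/*3A" & geno$observed == "*1/*3A")[1:12]
  s_idx <- which(seq_$imputed == "*1/*3A" & seq_$observed == "*1/*3A")[1:12]
  geno$sample_id[g_idx] <- shared_ids
  seq_$sample_id[s_idx] <- shared_ids
  list(genotyping = geno, sequencing = seq_,
       merged = merge_validation_sets(geno, seq_))
}
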