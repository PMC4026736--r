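# Frequency reporting: allele, genotype and phenotype count/percentage
# tables stratified by ancestry group.  The genotype table is the single
# counting path; allele and phenotype tables are deterministic aggregations
# of it, so allele conservation holds by construction.

.all_genotypes <- function() {
  s <- star_alleles()
  out <- character(0)
  for (i in seq_along(s)) for (j in i:length(s))
    out <- c(out, paste(s[i], s[j], sep = "/"))
  out  # 10 unordered pairs in canonical order
}

#' Allele counts derived from a genotype count table
#'
#' Each sample contributes two allele counts; a homozygote contributes two
#' copies of its allele.
#'
#' @param gt_counts Integer matrix, rows = diplotype strings, columns =
#'   strata.
#' @return 4 x strata integer matrix of allele counts (rows
#'   `star_alleles()`); column sums equal `2 * colSums(gt_counts)`.
#' @export
allele_counts_from_genotypes <- function(gt_counts) {
  rows <- rownames(gt_counts)
  parts <- strsplit(rows, "/", fixed = TRUE)
  if (!all(unlist(parts) %in% star_alleles()))
    stop("rownames must be star diplotypes")
  out <- matrix(0L, 4L, ncol(gt_counts),
                dimnames = list(star_alleles(), colnames(gt_counts)))
  for (i in seq_along(rows)) for (a in parts[[i]])
    out[a, ] <- out[a, ] + gt_counts[i, ]
  out
}

#' Phenotype counts derived from a genotype count table
#'
#' normal = zero defective alleles (`*1/*1`); intermediate = one (the
#' `*1/*3x` heterozygotes); low = two (all remaining diplotypes).
#'
#' @inheritParams allele_counts_from_genotypes
#' @return 3 x strata integer matrix, rows normal/intermediate/low.
#' @export
phenotype_counts_from_genotypes <- function(gt_counts) {
  dc <- defective_count(rownames(gt_counts))
  out <- matrix(0L, 3L, ncol(gt_counts),
                dimnames = list(c("normal", "intermediate", "low"),
                                colnames(gt_counts)))
  for (k in 0:2)
    out[k + 1L, ] <- as.integer(colSums(gt_counts[dc == k, , drop = FALSE]))
  out
}

.int_colsums <- function(m)
  stats::setNames(as.integer(colSums(m)), colnames(m))

.freq_table <- function(counts, denominators, no_calls, what) {
  pct <- sweep(counts, 2, denominators, "/") * 100
  pct[, denominators == 0] <- 0
  structure(list(counts = counts, percents = pct,
                 denominators = denominators, no_calls = no_calls,
                 what = what,
                 empty_strata = colnames(counts)[denominators == 0]),
            class = "tpmt_freq_table")
}

#' @export
print.tpmt_freq_table <- function(x, digits = 2, ...) {
  cat(sprintf("%s frequency table\n", x$what))
  cells <- matrix(sprintf("%d (%.*f)", x$counts, digits, round(x$percents, digits)),
                  nrow(x$counts), dimnames = dimnames(x$counts))
  print(cells, quote = FALSE)
  if (any(x$no_calls > 0))
    cat("no-calls excluded from denominators:",
        paste(sprintf("%s=%d", names(x$no_calls), x$no_calls), collapse = ", "),
        "\n")
  if (length(x$empty_strata))
    cat("empty strata (percents reported as 0):",
        paste(x$empty_strata, collapse = ", "), "\n")
  invisible(x)
}

.tabulate_genotypes <- function(diplotype, group) {
  group <- as.character(group)
  bad <- setdiff(unique(group), super_groups())
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  called <- !is.na(diplotype)
  gt <- factor(diplotype[called], levels = .all_genotypes())
  if (anyNA(gt)) stop("malformed diplotype label")
  g <- factor(group[called], levels = super_groups())
  counts <- as.matrix(unclass(table(gt, g)))
  counts <- cbind(counts, Total = as.integer(rowSums(counts)))
  nc <- table(factor(group[!called], levels = super_groups()))
  no_calls <- c(as.integer(nc), sum(nc))
  names(no_calls) <- c(super_groups(), "Total")
  storage.mode(counts) <- "integer"
  list(counts = counts, no_calls = no_calls)
}

#' Genotype frequency table by ancestry group
#'
#' @param diplotype Character vector of star diplotypes (`NA` = no-call;
#'   no-calls are excluded from denominators and reported separately).
#' @param group Ancestry super-group per sample.
#' @param drop_empty_rows Drop diplotype rows with zero total count.
#' @return A `tpmt_freq_table` (counts, percents per called sample,
#'   denominators, no-call accounting).
#' @export
genotype_frequency_table <- function(diplotype, group, drop_empty_rows = TRUE) {
  tab <- .tabulate_genotypes(diplotype, group)
  counts <- tab$counts
  if (drop_empty_rows) counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  .freq_table(counts, .int_colsums(counts), tab$no_calls, "genotypes")
}

#' Allele frequency table by ancestry group
#'
#' Aggregated from the genotype tabulation; denominators are 2 x called
#' samples per stratum.
#'
#' @inheritParams genotype_frequency_table
#' @return A `tpmt_freq_table`.
#' @export
allele_frequency_table <- function(diplotype, group) {
  tab <- .tabulate_genotypes(diplotype, group)
  counts <- allele_counts_from_genotypes(tab$counts)
  .freq_table(counts, .int_colsums(counts), tab$no_calls, "alleles")
}

#' Phenotype frequency table by ancestry group
#'
#' Aggregated from the genotype tabulation (no independent counting path).
#'
#' @inheritParams genotype_frequency_table
#' @return A `tpmt_freq_table` with rows normal/intermediate/low.
#' @export
phenotype_frequency_table <- function(diplotype, group) {
  tab <- .tabulate_genotypes(diplotype, group)
  counts <- phenotype_counts_from_genotypes(tab$counts)
  .freq_table(counts, .int_colsums(counts), tab$no_calls, "phenotypes")
}

#' Write a frequency table as TSV (counts and percents as separate columns)
#'
#' @param x A `tpmt_freq_table`.
#' @param path Output file.
#' @param digits Decimal places for percents (round-half-even).
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(x, path, digits = 2) {
  df <- data.frame(row = rownames(x$counts), check.names = FALSE)
  for (s in colnames(x$counts)) {
    df[[paste0(s, "_n")]] <- x$counts[, s]
    df[[paste0(s, "_pct")]] <- round(x$percents[, s], digits)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
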