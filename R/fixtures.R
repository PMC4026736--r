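# Published reference tables shipped as plain-text fixtures under
# inst/extdata.  These are the study's printed count tables for an 87,979
# sample biobank cohort; they serve as regression anchors for the report
# and validation modules and as default frequency parameters for the
# simulator.

.read_count_matrix <- function(file) {
  path <- system.file("extdata", file, package = "tpmtstar", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Published reference tables
#'
#' Loads the shipped count tables:
#' \describe{
#'   \item{table3_genotypes}{9 x 4 genotype counts by ancestry super-group
#'     (87,979 samples).}
#'   \item{table2_alleles_printed}{allele counts as printed, including the
#'     known 2-allele internal inconsistency of the `*1` total.}
#'   \item{table5_genotyping}{3 x 3 imputed-vs-genotyping confusion matrix
#'     (583 samples, diplotype resolution).}
#'   \item{table6_sequencing}{6 x 6 imputed-vs-Sanger confusion matrix
#'     (59 samples).}
#'   \item{table7_defective}{3 x 3 imputed-vs-observed matrix over
#'     defective-allele counts for the merged 630-sample validation set.}
#'   \item{star1_total_discrepancy}{difference between the `*1` total allele
#'     count derived from the genotype table (self-consistent) and the
#'     printed value; the genotype-derived count is authoritative here.}
#' }
#'
#' @return Named list of integer matrices plus the discrepancy flag.
#' @export
tpmt_fixtures <- function() {
  t3 <- .read_count_matrix("table3_genotype_counts.tsv")
  t2p <- .read_count_matrix("table2_allele_counts_printed.tsv")
  t5 <- .read_count_matrix("table5_concordance_genotyping.tsv")
  t6 <- .read_count_matrix("table6_concordance_sequencing.tsv")
  t7 <- .read_count_matrix("table7_defective_alleles.tsv")
  derived_star1_total <- sum(allele_counts_from_genotypes(t3)["*1", ])
  list(
    table3_genotypes = t3,
    table2_alleles_printed = t2p,
    table5_genotyping = t5,
    table6_sequencing = t6,
    table7_defective = t7,
    n_samples = sum(t3),
    star1_total_discrepancy = as.integer(derived_star1_total - t2p["*1", "Total"])
  )
}
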