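# Star-allele definitions and genotype -> diplotype translation for TPMT.
#
# The two causal SNPs are rs1800460 (C>T, p.Ala154Thr) and rs1142345 (T>C,
# p.Tyr240Cys).  A haplotype is named by the alleles it carries at the pair
# (rs1800460, rs1142345):
#   *1  = (C, T)   wild type
#   *3A = (T, C)   both variants
#   *3B = (T, T)   rs1800460 variant only
#   *3C = (C, C)   rs1142345 variant only

#' Star alleles recognised by the package
#'
#' The four TPMT star alleles handled here, in canonical display order.
#' Alleles beyond *1/*3A/*3B/*3C (e.g. *2, *6, *8) are out of scope and
#' always translate to a no-call.
#'
#' @return Character vector `c("*1", "*3A", "*3B", "*3C")`.
#' @export
star_alleles <- function() c("*1", "*3A", "*3B", "*3C")

# defining alleles at (rs1800460, rs1142345), genomic-strand letters
.star_def <- list(
  "*1"  = c("C", "T"),
  "*3A" = c("T", "C"),
  "*3B" = c("T", "T"),
  "*3C" = c("C", "C")
)

#' Translate one haplotype to a star allele
#'
#' @param a460 Allele at rs1800460, `"C"` or `"T"` (or 0/1 numeric codes,
#'   0 = reference C).
#' @param a345 Allele at rs1142345, `"T"` or `"C"` (or 0/1 numeric codes,
#'   0 = reference T).
#' @return Character vector of star-allele names.
#' @examples
#' haplotype_to_star("C", "T")  # "*1"
#' haplotype_to_star("T", "C")  # "*3A"
#' @export
haplotype_to_star <- function(a460, a345) {
  if (is.numeric(a460)) a460 <- c("C", "T")[a460 + 1L]
  if (is.numeric(a345)) a345 <- c("T", "C")[a345 + 1L]
  if (!all(a460 %in% c("C", "T")) || !all(a345 %in% c("T", "C")))
    stop("alleles must be C/T at rs1800460 and T/C at rs1142345")
  out <- character(length(a460))
  out[a460 == "C" & a345 == "T"] <- "*1"
  out[a460 == "T" & a345 == "C"] <- "*3A"
  out[a460 == "T" & a345 == "T"] <- "*3B"
  out[a460 == "C" & a345 == "C"] <- "*3C"
  out
}

#' Defining alleles of a star allele
#'
#' Inverse of [haplotype_to_star()]: the (rs1800460, rs1142345) allele pair
#' that defines each star allele.
#'
#' @param star Star-allele name(s), e.g. `"*3A"`.
#' @return For a single name, a length-2 character vector; for several, a
#'   2-row matrix with rows `rs1800460` and `rs1142345`.
#' @export
star_to_haplotype <- function(star) {
  bad <- setdiff(star, names(.star_def))
  if (length(bad)) stop("unknown star allele: ", paste(bad, collapse = ", "))
  m <- vapply(star, function(s) .star_def[[s]], character(2))
  rownames(m) <- c("rs1800460", "rs1142345")
  if (length(star) == 1L) drop(m) else m
}

#' Canonical unordered star-allele diplotype string
#'
#' @param a,b Star-allele names (vectors recycle).
#' @return Character like `"*1/*3A"`, ordered `*1 < *3A < *3B < *3C`.
#' @export
star_diplotype <- function(a, b) {
  ord <- star_alleles()
  ia <- match(a, ord); ib <- match(b, ord)
  if (anyNA(ia) || anyNA(ib)) stop("unknown star allele")
  paste(ord[pmin(ia, ib)], ord[pmax(ia, ib)], sep = "/")
}

#' Number of defective alleles in a diplotype
#'
#' Defective = any allele other than `*1` (*3A, *3B, *3C all confer
#' reduced activity).
#'
#' @param diplotype Diplotype strings such as `"*1/*3C"`; `NA` for no-call.
#' @return Integer 0/1/2 (NA for no-call).
#' @export
defective_count <- function(diplotype) {
  parts <- strsplit(diplotype, "/", fixed = TRUE)
  vapply(seq_along(diplotype), function(i) {
    if (is.na(diplotype[i])) return(NA_integer_)
    p <- parts[[i]]
    if (length(p) != 2L || !all(p %in% star_alleles()))
      stop("malformed diplotype: ", diplotype[i])
    sum(p != "*1")
  }, integer(1))
}

#' TPMT activity phenotype of a diplotype
#'
#' Trimodal activity classes: 0 defective alleles = normal, 1 =
#' intermediate, 2 = low.
#'
#' @param diplotype Diplotype strings; `NA` propagates as no-call.
#' @return Character `"normal"`, `"intermediate"` or `"low"` (NA for
#'   no-call).
#' @export
phenotype_of <- function(diplotype) {
  c("normal", "intermediate", "low")[defective_count(diplotype) + 1L]
}

.norm_gt <- function(g, letters) {
  # sort the two allele letters into canonical order (e.g. "TC" == "CT")
  if (is.na(g) || g %in% c(".", "./.", "")) return(NA_character_)
  a <- strsplit(g, "")[[1]]
  if (length(a) != 2L || !all(a %in% letters))
    stop("malformed genotype symbol: ", g)
  paste(a[order(match(a, letters))], collapse = "")
}

#' Translate unphased genotypes at the two SNPs into a star diplotype
#'
#' Implements the unphased assignment rule: at the double heterozygote
#' (rs1800460 CT with rs1142345 TC) the two variant alleles are assigned in
#' cis, i.e. `*1/*3A`, never the alternative phase `*3B/*3C`.  This
#' ambiguity rule reflects the strong linkage disequilibrium between the
#' two variants and their low frequency, which makes the *3A haplotype far
#' more likely than a *3B/*3C pair.
#'
#' @param g460 Genotype at rs1800460: `"CC"`, `"CT"` or `"TT"` (allele
#'   order irrelevant); `NA` or `"."` for missing.
#' @param g345 Genotype at rs1142345: `"TT"`, `"TC"` or `"CC"`; `NA` or
#'   `"."` for missing.
#' @return Character vector of diplotype strings; `NA` (no-call) wherever
#'   either genotype is missing.
#' @examples
#' diplotype_from_genotypes("CT", "TC")  # "*1/*3A"
#' diplotype_from_genotypes("TT", "TC")  # "*3A/*3B"
#' @export
diplotype_from_genotypes <- function(g460, g345) {
  n <- max(length(g460), length(g345))
  g460 <- rep_len(g460, n); g345 <- rep_len(g345, n)
  lut <- c(
    "CC.TT" = "*1/*1",   "CC.TC" = "*1/*3C",  "CC.CC" = "*3C/*3C",
    "CT.TT" = "*1/*3B",  "CT.TC" = "*1/*3A",  "CT.CC" = "*3A/*3C",
    "TT.TT" = "*3B/*3B", "TT.TC" = "*3A/*3B", "TT.CC" = "*3A/*3A"
  )
  vapply(seq_len(n), function(i) {
    a <- .norm_gt(g460[i], c("C", "T"))
    b <- .norm_gt(g345[i], c("T", "C"))
    if (is.na(a) || is.na(b)) return(NA_character_)
    unname(lut[[paste(a, b, sep = ".")]])
  }, character(1))
}

#' Translate unphased genotypes given as alt-allele dosages
#'
#' Convenience wrapper around [diplotype_from_genotypes()] for 0/1/2 coded
#' calls (alt = T at rs1800460, alt = C at rs1142345).
#'
#' @param d460,d345 Integer dosages 0/1/2 (NA = no-call).
#' @return Diplotype strings as in [diplotype_from_genotypes()].
#' @export
diplotype_from_dosages <- function(d460, d345) {
  g460 <- c("CC", "CT", "TT")[d460 + 1L]
  g345 <- c("TT", "TC", "CC")[d345 + 1L]
  diplotype_from_genotypes(g460, g345)
}

#' Translate a phased haplotype pair into a star diplotype
#'
#' The phased path applies [haplotype_to_star()] to each haplotype, so a
#' (T,T)+(C,C) pair yields `*3B/*3C` where the unphased rule would say
#' `*1/*3A` — keeping both paths makes the effect of the ambiguity rule
#' observable.
#'
#' @param hapA,hapB Length-2 vectors `(rs1800460 allele, rs1142345 allele)`,
#'   letters or 0/1 codes.
#' @return A single diplotype string.
#' @export
diplotype_from_phased <- function(hapA, hapB) {
  star_diplotype(haplotype_to_star(hapA[1], hapA[2]),
                 haplotype_to_star(hapB[1], hapB[2]))
}
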