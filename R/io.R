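# VCF and TSV input/output.  Reading goes through vcfR; writing emits
# plain VCF 4.2 text with GT and optional GP (genotype probability
# triplet) and DS (dosage) FORMAT fields.

#' Write genotypes to a VCF file
#'
#' @param variants data.frame with columns id, chrom, pos, ref, alt.
#' @param gt Sample x variant matrix of GT strings (`"0|1"`, `"1/0"`,
#'   `"./."`, ...); row names are sample ids.
#' @param path Output path.
#' @param gp Optional list of three sample x variant matrices (p0, p1,
#'   p2) written as the GP field.
#' @param ds Optional sample x variant dosage matrix written as DS.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, gt, path, gp = NULL, ds = NULL) {
  samples <- rownames(gt) %||% sprintf("S%04d", seq_len(nrow(gt)))
  fmt <- c("GT", if (!is.null(gp)) "GP", if (!is.null(ds)) "DS")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tpmtstar",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(gp))
      '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype probabilities">',
    if (!is.null(ds))
      '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alt dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(variants)), function(v) {
    cells <- gt[, v]
    if (!is.null(gp))
      cells <- paste(cells, sprintf("%.6g,%.6g,%.6g",
                                    gp[[1]][, v], gp[[2]][, v], gp[[3]][, v]),
                     sep = ":")
    if (!is.null(ds))
      cells <- paste(cells, sprintf("%.6g", ds[, v]), sep = ":")
    paste(c(variants$chrom[v], variants$pos[v], variants$id[v],
            variants$ref[v], variants$alt[v], ".", "PASS", ".",
            paste(fmt, collapse = ":"), cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a VCF file
#'
#' Wraps `vcfR::read.vcfR` and unpacks GT (preserving phase and missing
#' calls), GP and DS when present.
#'
#' @param path VCF path (plain or gzipped).
#' @return List: `variants` (id, chrom, pos, ref, alt), `gt` (sample x
#'   variant GT strings), `phased` (logical matrix), `hapA`/`hapB`
#'   (integer allele matrices, NA where missing), `dosage` (hapA + hapB),
#'   `gp` (list p0/p1/p2 or NULL), `ds` (matrix or NULL), `samples`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, stringsAsFactors = FALSE)
  gt_vs <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  gt <- t(gt_vs)  # sample x variant
  colnames(gt) <- variants$id
  parse_allele <- function(a) {
    out <- rep(NA_integer_, length(a))
    ok <- a %in% c("0", "1")
    out[ok] <- as.integer(a[ok])
    out
  }
  toks <- regmatches(gt, regexec("^([0-9.])([|/])([0-9.])$", gt))
  a1 <- matrix(vapply(toks, function(t) if (length(t)) t[2] else NA_character_,
                      ""), nrow(gt), dimnames = dimnames(gt))
  sep <- matrix(vapply(toks, function(t) if (length(t)) t[3] else NA_character_,
                       ""), nrow(gt), dimnames = dimnames(gt))
  a2 <- matrix(vapply(toks, function(t) if (length(t)) t[4] else NA_character_,
                      ""), nrow(gt), dimnames = dimnames(gt))
  hapA <- matrix(parse_allele(a1), nrow(gt), dimnames = dimnames(gt))
  hapB <- matrix(parse_allele(a2), nrow(gt), dimnames = dimnames(gt))
  fmt <- v@gt[, "FORMAT"]
  gp <- NULL
  if (any(grepl("(^|:)GP(:|$)", fmt))) {
    raw <- t(vcfR::extract.gt(v, element = "GP"))
    colnames(raw) <- variants$id
    split3 <- function(k) matrix(vapply(strsplit(raw, ",", fixed = TRUE),
                                        function(x) as.numeric(x[k]),
                                        numeric(1)),
                                 nrow(raw), dimnames = dimnames(raw))
    gp <- list(p0 = split3(1), p1 = split3(2), p2 = split3(3))
  }
  ds <- NULL
  if (any(grepl("(^|:)DS(:|$)", fmt))) {
    ds <- t(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
    colnames(ds) <- variants$id
  }
  list(variants = variants, gt = gt, phased = sep == "|",
       hapA = hapA, hapB = hapB, dosage = hapA + hapB,
       gp = gp, ds = ds, samples = rownames(gt))
}

#' GT strings from phased haplotype allele matrices
#'
#' @param hapA,hapB Integer 0/1 matrices (NA = missing allele).
#' @param phased Use `"|"` (TRUE) or `"/"` separators.
#' @return Character matrix of GT strings (`"./."` where missing).
#' @export
gt_strings <- function(hapA, hapB, phased = TRUE) {
  sep <- if (phased) "|" else "/"
  chr <- function(m) ifelse(is.na(m), ".", as.character(m))
  out <- matrix(paste(chr(hapA), chr(hapB), sep = sep),
                nrow(hapA), dimnames = dimnames(hapA))
  out
}

#' Write a haplotype panel as a phased VCF
#'
#' Consecutive haplotype rows are paired into diploid records (each
#' reference sample contributes two haplotypes).
#'
#' @param panel A `haplotype_panel` with an even number of haplotypes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  H <- panel$haplotypes
  if (nrow(H) %% 2 != 0) stop("panel must have an even number of haplotypes")
  odd <- seq(1, nrow(H), by = 2)
  gt <- gt_strings(H[odd, , drop = FALSE], H[odd + 1L, , drop = FALSE])
  rownames(gt) <- sprintf("REF%04d", seq_along(odd))
  write_vcf(panel$variants, gt, path)
}

#' Read a phased VCF as a haplotype panel
#'
#' @param path VCF with fully phased GT fields.
#' @param hap_population Population label per haplotype (recycled from one
#'   value), 2 haplotypes per sample.
#' @return A `haplotype_panel`.
#' @export
read_panel_vcf <- function(path, hap_population = "panel") {
  v <- read_vcf(path)
  if (!all(v$phased, na.rm = TRUE)) stop("panel VCF must be fully phased")
  n <- nrow(v$hapA)
  H <- matrix(NA_integer_, 2L * n, ncol(v$hapA),
              dimnames = list(NULL, colnames(v$hapA)))
  H[seq(1, 2 * n, 2), ] <- v$hapA
  H[seq(2, 2 * n, 2), ] <- v$hapB
  variants <- v$variants
  structure(list(variants = variants, haplotypes = H,
                 hap_population = rep_len(hap_population, 2L * n)),
            class = "haplotype_panel")
}
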