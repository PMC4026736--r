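# Synthetic data generation: locus haplotype panels with star-allele cores
# and tagging flank markers, diploid study cohorts typed on two array
# designs, Balding-Nichols ancestry markers, and X-chromosome markers for
# sex inference.  Everything is seeded and the pre-corruption truth is
# retained, so downstream stages can be tested by parameter recovery.

.LOCUS_START <- 18128545L
.LOCUS_END <- 18155374L
.POS_460 <- 18139228L  # rs1800460 C>T
.POS_345 <- 18130918L  # rs1142345 T>C

#' Variant definitions for the simulated TPMT locus
#'
#' The two causal SNPs plus `n_flank` tag markers spread across the locus
#' (chr6:18,128,545-18,155,374).  Tag markers alternate in tagging
#' rs1800460 and rs1142345 and are probed on both array designs; among the
#' causal SNPs only rs1800460 is probed, and only on the quad-like design.
#'
#' @param n_flank Number of flanking tag markers (>= 0).
#' @return data.frame with columns id, chrom, pos, ref, alt, tags
#'   (index of the tagged causal SNP, NA for causal rows), and logical
#'   columns `quad_like`, `x550_like` saying which designs probe it.
#' @export
tpmt_variants <- function(n_flank = 10L) {
  if (n_flank < 0) stop("n_flank must be >= 0")
  pos_f <- if (n_flank > 0)
    as.integer(round(seq(.LOCUS_START + 500L, .LOCUS_END - 500L,
                         length.out = n_flank)))
  else integer(0)
  pos_f[pos_f %in% c(.POS_460, .POS_345)] <-
    pos_f[pos_f %in% c(.POS_460, .POS_345)] + 1L
  df <- data.frame(
    id = c("rs1142345", "rs1800460",
           sprintf("tag%03d", seq_len(n_flank))),
    chrom = "6",
    pos = c(.POS_345, .POS_460, pos_f),
    ref = c("T", "C", rep("A", n_flank)),
    alt = c("C", "T", rep("G", n_flank)),
    tags = c(NA_integer_, NA_integer_,
             rep_len(c(2L, 1L), n_flank)),  # tag rs1800460, rs1142345, ...
    stringsAsFactors = FALSE
  )
  df <- df[order(df$pos), ]
  rownames(df) <- NULL
  df$quad_like <- df$id != "rs1142345"
  df$x550_like <- !(df$id %in% c("rs1142345", "rs1800460"))
  df
}

#' Chip designs: which variants each array probes
#'
#' Two designs mirroring the study arrays: the quad-like design probes
#' rs1800460 (not rs1142345); the 550-like design probes neither causal
#' SNP.  Both probe all flanking tag markers.
#'
#' @param variants A [tpmt_variants()] data.frame.
#' @return Named list of character vectors of probed variant ids.
#' @export
chip_designs <- function(variants) {
  list("quad-like" = variants$id[variants$quad_like],
       "550-like" = variants$id[variants$x550_like])
}

#' Build a phased locus haplotype panel
#'
#' Each haplotype carries a star-allele core (the rs1800460/rs1142345
#' allele pair defined by a star allele drawn from the population's
#' `star_freqs`) plus flanking tag markers generated as noisy copies of
#' their tagged causal SNP: a flank copies the causal allele with
#' probability `ld_r` and carries the flipped allele otherwise, giving a
#' learnable local LD structure.
#'
#' @param pop_specs List of [population_spec()] objects.
#' @param n_haps_per_pop Haplotypes per population (>= 2).
#' @param n_flank Number of flanking tag markers.
#' @param ld_r Copy fidelity of flank markers in (0.5, 1]; scalar or one
#'   value per flank marker.
#' @param seed Integer seed; identical inputs give identical panels.
#' @return A `haplotype_panel`: list(variants, haplotypes (hap x variant
#'   0/1 matrix), hap_population).
#' @export
build_locus_panel <- function(pop_specs, n_haps_per_pop = 500L,
                              n_flank = 10L, ld_r = 0.95, seed = 1L) {
  if (n_haps_per_pop < 2) stop("n_haps_per_pop must be >= 2")
  if (inherits(pop_specs, "population_spec")) pop_specs <- list(pop_specs)
  variants <- tpmt_variants(n_flank)
  ld_r <- rep_len(ld_r, n_flank)
  set.seed(seed)
  haps <- list(); pops <- character(0)
  for (ps in pop_specs) {
    stars <- sample(star_alleles(), n_haps_per_pop, replace = TRUE,
                    prob = ps$star_freqs)
    core <- vapply(stars, function(s) {
      al <- star_to_haplotype(s)  # (rs1800460, rs1142345) letters
      c(rs1800460 = as.integer(al[1] == "T"),
        rs1142345 = as.integer(al[2] == "C"))
    }, integer(2))
    h <- matrix(0L, n_haps_per_pop, nrow(variants),
                dimnames = list(NULL, variants$id))
    h[, "rs1800460"] <- core["rs1800460", ]
    h[, "rs1142345"] <- core["rs1142345", ]
    flank_rows <- which(!is.na(variants$tags))
    for (j in seq_along(flank_rows)) {
      v <- flank_rows[j]
      causal <- c("rs1142345", "rs1800460")[variants$tags[v]]
      flip <- stats::runif(n_haps_per_pop) > ld_r[j]
      h[, v] <- ifelse(flip, 1L - h[, causal], h[, causal])
    }
    haps[[ps$name]] <- h
    pops <- c(pops, rep(ps$name, n_haps_per_pop))
  }
  structure(list(variants = variants,
                 haplotypes = do.call(rbind, haps),
                 hap_population = pops),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype panel: %d haplotypes x %d variants (%s)\n",
              nrow(x$haplotypes), nrow(x$variants),
              paste(names(table(x$hap_population)), collapse = ", ")))
  invisible(x)
}

.flip_bits <- function(m, rate) {
  if (rate <= 0) return(m)
  flip <- matrix(stats::runif(length(m)) < rate, nrow(m))
  flip[is.na(m)] <- FALSE
  m[flip] <- 1L - m[flip]
  m
}

#' Simulate a diploid study cohort from a haplotype panel
#'
#' Each sample draws two haplotypes (with replacement, i.e. random mating
#' within population) from its population's pool in `panel`.  Samples are
#' assigned to a chip design; markers the design does not probe are masked
#' (NA) in the typed output.  Typed alleles are then corrupted:
#' genotyping errors flip alleles independently at `genotyping_error_rate`,
#' and switch errors exchange the suffixes of a sample's two haplotypes at
#' random typed positions at `switch_error_rate` per position.  Truth is
#' recorded before corruption.
#'
#' @param panel A `haplotype_panel` whose `hap_population` covers every
#'   population in `pop_specs`.
#' @param pop_specs List of [population_spec()] (uses `name`,
#'   `super_group`, `n_samples`).
#' @param chip_fraction_quad Fraction of samples assigned to the quad-like
#'   design (remainder 550-like); default 0.5, approximating the near-even
#'   split of the study arrays.
#' @param genotyping_error_rate,switch_error_rate Probabilities in [0, 1).
#' @param seed Integer seed.
#' @return List with `typed` (per chip: list(sample_ids, hapA, hapB
#'   matrices over probed variants, NA at unprobed)), `genotypes`
#'   (unphased sample x typed-variant dosage matrix, NA where unprobed),
#'   `truth` data.frame (sample_id, population, super_group, sex, chip,
#'   star_a, star_b, diplotype), and `variants`.
#' @export
simulate_cohort <- function(panel, pop_specs, chip_fraction_quad = 0.5,
                            genotyping_error_rate = 0,
                            switch_error_rate = 0, seed = 1L) {
  if (!inherits(panel, "haplotype_panel") || nrow(panel$haplotypes) == 0)
    stop("empty or invalid panel")
  if (inherits(pop_specs, "population_spec")) pop_specs <- list(pop_specs)
  for (r in c(genotyping_error_rate, switch_error_rate))
    if (r < 0 || r >= 1) stop("error rates must be in [0, 1)")
  set.seed(seed)
  variants <- panel$variants
  designs <- chip_designs(variants)
  n_total <- sum(vapply(pop_specs, `[[`, integer(1), "n_samples"))
  hapA <- matrix(NA_integer_, n_total, nrow(variants),
                 dimnames = list(NULL, variants$id))
  hapB <- hapA
  truth <- data.frame(sample_id = sprintf("S%05d", seq_len(n_total)),
                      population = NA_character_, super_group = NA_character_,
                      sex = NA_character_, chip = NA_character_,
                      star_a = NA_character_, star_b = NA_character_,
                      diplotype = NA_character_, stringsAsFactors = FALSE)
  i <- 0L
  for (ps in pop_specs) {
    pool <- which(panel$hap_population == ps$name)
    if (length(pool) < 2) stop("panel has no haplotypes for ", ps$name)
    idx <- i + seq_len(ps$n_samples)
    hapA[idx, ] <- panel$haplotypes[sample(pool, ps$n_samples, TRUE), ]
    hapB[idx, ] <- panel$haplotypes[sample(pool, ps$n_samples, TRUE), ]
    truth$population[idx] <- ps$name
    truth$super_group[idx] <- ps$super_group
    i <- i + ps$n_samples
  }
  truth$sex <- sample(c("male", "female"), n_total, TRUE)
  truth$chip <- sample(names(designs), n_total, TRUE,
                       prob = c(chip_fraction_quad, 1 - chip_fraction_quad))
  star_a <- haplotype_to_star(hapA[, "rs1800460"], hapA[, "rs1142345"])
  star_b <- haplotype_to_star(hapB[, "rs1800460"], hapB[, "rs1142345"])
  truth$star_a <- star_a
  truth$star_b <- star_b
  truth$diplotype <- star_diplotype(star_a, star_b)

  typed <- list()
  genotypes <- matrix(NA_integer_, n_total, nrow(variants),
                      dimnames = list(truth$sample_id, variants$id))
  for (chip in names(designs)) {
    rows <- which(truth$chip == chip)
    probed <- variants$id %in% designs[[chip]]
    tA <- hapA[rows, , drop = FALSE]; tA[, !probed] <- NA_integer_
    tB <- hapB[rows, , drop = FALSE]; tB[, !probed] <- NA_integer_
    tA <- .flip_bits(tA, genotyping_error_rate)
    tB <- .flip_bits(tB, genotyping_error_rate)
    if (switch_error_rate > 0) {
      pcols <- which(probed)
      for (r in seq_along(rows)) {
        sw <- pcols[stats::runif(length(pcols)) < switch_error_rate]
        for (s in sw) {  # exchange suffixes from position s onward
          cols <- pcols[pcols >= s]
          tmp <- tA[r, cols]; tA[r, cols] <- tB[r, cols]; tB[r, cols] <- tmp
        }
      }
    }
    genotypes[rows, ] <- tA + tB
    typed[[chip]] <- list(sample_ids = truth$sample_id[rows],
                          hapA = tA, hapB = tB,
                          probed_ids = variants$id[probed])
  }
  list(typed = typed, genotypes = genotypes, truth = truth,
       truth_haplotypes = list(hapA = hapA, hapB = hapB),
       variants = variants)
}

#' Simulate population-differentiated ancestry markers
#'
#' Balding-Nichols model: for each marker an ancestral frequency p is
#' drawn from `ancestral_freq_fn`, and each population's frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance
#' p(1-p)F.  Genotypes are Binomial(2, pop frequency).  A labelled
#' reference subset is generated for nearest-neighbor classification.
#'
#' @param n_markers Number of markers (>= 1).
#' @param pop_specs List of [population_spec()] (uses `name`, `n_samples`).
#' @param fst Fixation index in [0, 1); 0 means no differentiation.
#' @param n_ref_per_pop Labelled reference samples per population.
#' @param ancestral_freq_fn Function(n) returning n ancestral frequencies
#'   in (0, 1); default Uniform(0.1, 0.9).
#' @param seed Integer seed.
#' @return List: `study` (sample x marker dosage matrix), `study_pop`
#'   (true labels, for recovery checks only), `ref`, `ref_pop`,
#'   `pop_freqs` (population x marker).
#' @export
simulate_ancestry_markers <- function(n_markers, pop_specs, fst = 0.1,
                                      n_ref_per_pop = 50L,
                                      ancestral_freq_fn = function(n)
                                        stats::runif(n, 0.1, 0.9),
                                      seed = 1L) {
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (inherits(pop_specs, "population_spec")) pop_specs <- list(pop_specs)
  set.seed(seed)
  p_anc <- ancestral_freq_fn(n_markers)
  pops <- vapply(pop_specs, `[[`, character(1), "name")
  pop_freqs <- matrix(NA_real_, length(pops), n_markers,
                      dimnames = list(pops, NULL))
  for (k in seq_along(pops)) {
    pop_freqs[k, ] <- if (fst == 0) p_anc else
      stats::rbeta(n_markers, p_anc * (1 - fst) / fst,
                   (1 - p_anc) * (1 - fst) / fst)
  }
  draw <- function(n_per_pop) {
    g <- matrix(NA_integer_, sum(n_per_pop), n_markers)
    lab <- character(sum(n_per_pop)); i <- 0L
    for (k in seq_along(pops)) {
      for (r in seq_len(n_per_pop[k])) {
        i <- i + 1L
        g[i, ] <- stats::rbinom(n_markers, 2L, pop_freqs[k, ])
        lab[i] <- pops[k]
      }
    }
    list(g = g, lab = lab)
  }
  ref <- draw(rep(n_ref_per_pop, length(pops)))
  study <- draw(vapply(pop_specs, `[[`, integer(1), "n_samples"))
  list(study = study$g, study_pop = study$lab,
       ref = ref$g, ref_pop = ref$lab, pop_freqs = pop_freqs)
}

#' Simulate X-chromosome markers given true sexes
#'
#' Females are Binomial(2, p) at each marker; males are hemizygous, coded
#' diploid-style as 0 or 2 (never heterozygous before error).  Genotyping
#' error is a single-allele miscall: with probability `error_rate` one
#' allele of the recorded call flips, so male X heterozygosity equals
#' `error_rate` in expectation.
#'
#' @param n_markers Number of X markers (>= 1).
#' @param sex Character vector, `"male"`/`"female"` per sample.
#' @param maf_fn Function(n) for marker allele frequencies; default
#'   Uniform(0.1, 0.5).
#' @param error_rate Single-allele miscall probability in [0, 1).
#' @param seed Integer seed.
#' @return sample x marker dosage matrix.
#' @export
simulate_x_markers <- function(n_markers, sex,
                               maf_fn = function(n) stats::runif(n, 0.1, 0.5),
                               error_rate = 0, seed = 1L) {
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  set.seed(seed)
  p <- maf_fn(n_markers)
  n <- length(sex)
  g <- matrix(NA_integer_, n, n_markers)
  for (i in seq_len(n)) {
    g[i, ] <- if (sex[i] == "male") 2L * stats::rbinom(n_markers, 1L, p)
              else stats::rbinom(n_markers, 2L, p)
  }
  if (error_rate > 0) {
    err <- matrix(stats::runif(length(g)) < error_rate, n)
    up <- matrix(stats::runif(length(g)) < 0.5, n)  # which allele flips
    delta <- ifelse(g == 0L, 1L, ifelse(g == 2L, -1L, ifelse(up, 1L, -1L)))
    g[err] <- g[err] + delta[err]
  }
  g
}
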