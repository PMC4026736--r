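# Population nomenclature: HapMap3-style sub-population codes grouped into
# four ancestry super-groups.  Note GIH is grouped with the Hispanics,
# following the reference grouping used for the published cohort.

.pop_super_map <- c(
  CEU = "Caucasian", TSI = "Caucasian",
  ASW = "African", YRI = "African", MKK = "African", LWK = "African",
  MEX = "Hispanic", GIH = "Hispanic",
  CHD = "Asian", JPT = "Asian", CHB = "Asian"
)

#' Ancestry super-groups
#' @return `c("Caucasian", "African", "Hispanic", "Asian")`.
#' @export
super_groups <- function() c("Caucasian", "African", "Hispanic", "Asian")

#' Map a population label to its ancestry super-group
#'
#' Sub-population codes (CEU, TSI, ASW, YRI, MKK, LWK, MEX, GIH, CHD, JPT,
#' CHB) map to the four super-groups; a super-group name maps to itself.
#'
#' @param population Character vector of labels.
#' @return Character vector of super-group names.
#' @export
super_group_of <- function(population) {
  out <- ifelse(population %in% super_groups(),
                population,
                unname(.pop_super_map[population]))
  if (anyNA(out) && !anyNA(population))
    stop("unknown population label: ",
         paste(unique(population[is.na(out)]), collapse = ", "))
  out
}

#' Construct a population specification for the simulator
#'
#' @param name Population label.
#' @param star_freqs Named numeric vector of haplotype frequencies over
#'   `star_alleles()`; must sum to 1 (tolerance 1e-9).
#' @param n_samples Number of diploid samples to simulate.
#' @param super_group Ancestry super-group; defaults to
#'   `super_group_of(name)`.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, star_freqs, n_samples,
                            super_group = super_group_of(name)) {
  if (is.null(names(star_freqs)) ||
      !all(names(star_freqs) %in% star_alleles()))
    stop("star_freqs must be named with star alleles")
  if (any(star_freqs < 0) || abs(sum(star_freqs) - 1) > 1e-9)
    stop("star_freqs must be non-negative and sum to 1")
  if (!super_group %in% super_groups()) stop("unknown super_group")
  full <- stats::setNames(numeric(4), star_alleles())
  full[names(star_freqs)] <- star_freqs
  structure(list(name = name, super_group = super_group,
                 star_freqs = full, n_samples = as.integer(n_samples)),
            class = "population_spec")
}

#' Star-allele frequencies per super-group derived from the genotype fixture
#'
#' Allele frequencies computed from the shipped genotype count table
#' (counts / 2N per group), which is self-consistent, unlike the printed
#' allele table whose `*1` total is off by two alleles.
#'
#' @param group One of `super_groups()`, or `"Total"` for the pooled cohort.
#' @return Named frequency vector over `star_alleles()`, summing to 1.
#' @export
default_star_freqs <- function(group = "Total") {
  t3 <- tpmt_fixtures()$table3_genotypes
  ac <- allele_counts_from_genotypes(t3)
  counts <- if (group == "Total") rowSums(ac) else ac[, group]
  counts / sum(counts)
}

#' Default four-group population specification
#'
#' The four ancestry super-groups with fixture-derived star-allele
#' frequencies; group sizes proportional to the reference cohort
#' (Caucasian : African : Hispanic : Asian = 63,998 : 16,519 : 5,764 :
#' 1,698), scaled to `n_total`.
#'
#' @param n_total Total number of samples across groups.
#' @return List of `population_spec` objects.
#' @export
default_population_specs <- function(n_total = 2000L) {
  t3 <- tpmt_fixtures()$table3_genotypes
  sizes <- colSums(t3)
  n <- round(sizes / sum(sizes) * n_total)
  n[1] <- n_total - sum(n[-1])  # absorb rounding in the largest group
  lapply(super_groups(), function(g)
    population_spec(g, default_star_freqs(g), n[[g]], super_group = g))
}
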