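---
title: "Imputing TPMT star alleles: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing TPMT star alleles: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmtstar)
```

## The problem

Thiopurine methyltransferase (TPMT) inactivates thiopurine drugs
(azathioprine, 6-mercaptopurine, thioguanine). Individuals carrying one or
two defective *TPMT* alleles metabolize these drugs poorly and risk severe
myelosuppression at standard doses. The common defective alleles are
combinations of two missense SNPs on chromosome 6:

| star allele | rs1800460 (C>T) | rs1142345 (T>C) |
|---|---|---|
| \*1 (functional) | C | T |
| \*3A | T | C |
| \*3B | T | T |
| \*3C | C | C |

Large biobanks hold genome-wide array genotypes for huge cohorts, but the
common arrays probe at most one of these two SNPs. `tpmtstar` implements
the computational pipeline that turns such array data into TPMT
metabolizer phenotypes: reference-panel imputation of the two SNPs,
quality filtering, star-allele translation, population frequency
reporting, and validation against gold-standard genotypes — exercised on
synthetic cohorts with known truth, plus the published count tables
shipped as fixtures.

## Star-allele translation

A phased haplotype maps bijectively to a star allele through the table
above (`haplotype_to_star()`). Unphased genotype pairs are translated by
`diplotype_from_genotypes()` through a fixed 3×3 lookup. One cell is
genuinely ambiguous: the double heterozygote (rs1800460 CT with rs1142345
TC) is consistent with either \*1/\*3A or \*3B/\*3C. Because the two
variants are in strong linkage disequilibrium and \*3B and \*3C are rare,
the variant alleles are assigned in cis: the call is always \*1/\*3A. The
unphased rule is the primary path (it is what the published frequency
tables rest on); `diplotype_from_phased()` is provided so the effect of
the ambiguity rule is observable, and deliberately disagrees at a true
\*3B/\*3C pair.

Phenotype follows the trimodal activity model: 0 defective alleles →
normal, 1 → intermediate, 2 → low. \*2 (rs1800462) and rarer alleles are
out of scope; requesting them yields a no-call.

## The haplotype-copying imputation model

Imputation uses a Li–Stephens-style hidden Markov model: a study
haplotype is modelled as an imperfect mosaic of the $K$ reference-panel
haplotypes. Hidden state = which panel haplotype is being copied.

* **Transition** between adjacent markers: stay on the same haplotype
  with probability $1-\rho+\rho/K$, switch to any specific other with
  $\rho/K$. The locus spans ~27 kb, so a single per-interval switch
  probability is used rather than a genetic map; default
  $\rho = 0.01$.
* **Emission** at a typed marker: probability $1-\varepsilon$ if the
  copied haplotype carries the observed allele, $\varepsilon$ otherwise
  (default $\varepsilon = 0.001$). Untyped markers emit nothing.
* **Posterior extraction**: after the forward–backward pass, the
  posterior alt-allele probability at a marker is the state-posterior
  mass on panel haplotypes carrying the alt allele,
  $p_m = \sum_k \gamma_k(m)\, h_k(m)$. The copying-error rate enters
  through the emissions only; it is not smeared onto the extracted
  allele probability. This keeps the two-state worked example exact: with
  panel $\{(0,0),(1,1)\}$, an observed 0 at marker 1,
  $\varepsilon = 0.01$ and switch probability $0.05$, the posterior at
  the untyped marker 2 is $0.99 \times 0.05 + 0.01 \times 0.95 = 0.059$.

```{r hand-example}
panel <- structure(list(
  variants = data.frame(id = c("m1", "m2")),
  haplotypes = matrix(c(0L, 1L, 0L, 1L), 2,
                      dimnames = list(NULL, c("m1", "m2"))),
  hap_population = c("p", "p")), class = "haplotype_panel")
impute_haplotype(c(m1 = 0), panel, imputation_params(rho = 0.1, eps = 0.01))
```

Forward and backward vectors are rescaled at every marker, so the whole
computation stays in the linear domain without underflow; the scaling
constants cancel in the posterior. Study haplotypes arrive phased (the
generator emits phased typed data, optionally corrupted by switch
errors), mirroring a prephase-then-impute workflow; no phasing algorithm
is implemented.

The two haplotype posteriors $a, b$ of a sample combine under
independence into genotype probabilities
$(p_0,p_1,p_2) = \big((1-a)(1-b),\; a(1-b)+b(1-a),\; ab\big)$.

## Imputation quality: the info score

Per variant, with expected dosage $e_i = p_{i1} + 2p_{i2}$ and second
moment $f_i = p_{i1} + 4 p_{i2}$, the estimated alt frequency is
$\hat\theta = \sum_i e_i / 2N$ and

$$\mathrm{info} = 1 - \frac{\sum_i (f_i - e_i^2)}{2N\,\hat\theta(1-\hat\theta)},$$

the familiar ratio-of-variances measure: 1 when every genotype is
certain, 0 when the posteriors carry no information beyond the allele
frequency. Conventions: info $=1$ when $\hat\theta \in \{0, 1\}$ (no
variance left to explain), and the value is clamped to $[0,1]$.

Filtering is **inclusive** at the threshold (info $\ge 0.9$ retains;
the boundary value 0.90 is kept), and the threshold is configurable.
Two practical points discovered in testing and worth knowing:

* The measure degrades sharply as $\hat\theta \to 0$: a variant that is
  monomorphic-in-sample but carries tiny posterior noise can score near
  0 even when every call is effectively certain. For this reason the
  pipeline exempts markers *directly typed on a chip* from the filter on
  that chip — the info filter is quality control for *imputed*
  genotypes.
* For rare variants (the alt frequencies here are 0.1–5%), info hovers
  near the 0.9 boundary under the default synthetic tagging fidelity,
  so whole chips can legitimately lose rs1142345 in some seeds. Calls
  are then reported as no-calls, never guessed.

Hard calls take the posterior argmax when it reaches the call threshold
(default 0.9); exact ties and sub-threshold maxima are no-calls.

## Ancestry and sex inference

Population structure is inferred exactly as array pipelines do it:

1. **LD pruning** (`ld_prune()`): greedy left-to-right windowed removal
   (window 50 variants, step 5) of the later variant of any pair with
   squared dosage correlation above $r^2_{\max} = 0.2$. Only the
   $r^2$ threshold is externally prescribed; the windowing is the common
   default of array-QC tools.
2. **PCA** (`fit_pca()`): each variant's dosages are standardized by
   center $2\hat p$ and scale $\sqrt{2\hat p(1-\hat p)}$ with $\hat p$
   the *reference* panel frequency; components are the top
   right-singular vectors. Monomorphic (and zero-variance) variants are
   dropped and recorded. Study samples are projected with the reference
   frequencies so study structure cannot leak into the model. Default 10
   components.
3. **k-nearest neighbors** (`classify_population()`): majority label
   among the $k = 9$ Euclidean nearest labelled reference samples; ties
   fall back to the single nearest neighbor. Euclidean k-NN is invariant
   to component sign, so the classification does not depend on SVD sign
   conventions. Sub-population labels map to the four ancestry
   super-groups (Caucasian, African, Hispanic, Asian; GIH is grouped
   with the Hispanics, following the reference grouping).
4. **Sex** (`infer_sex()`): per sample
   $F = 1 - \mathrm{obsHet}/\mathrm{expHet}$ on X markers; male if
   $F > 0.8$, female if $F < 0.2$, otherwise undetermined. The 0.8/0.2
   band is the convention of standard array-QC software and produces an
   "undetermined" class as observed in real cohorts.

## What the synthetic generator emulates — and what it does not

The generator provides every input the pipeline needs, with known truth:

* **Locus panel** (`build_locus_panel()`): haplotypes carry a star-allele
  core drawn from population-specific frequencies. The default
  frequencies are derived from the shipped genotype count table
  (counts / 2N per ancestry group), which is self-consistent — the
  printed allele table's \*1 total is internally off by two alleles and
  is kept only as a flagged fixture. Flank "tag" markers are noisy
  copies of one causal SNP each (copy probability $r = 0.95$ by
  default, alternating between the two SNPs), giving the HMM a learnable
  local LD structure.
* **Cohort** (`simulate_cohort()`): two haplotypes per sample drawn with
  replacement from the population pool (random mating / HWE; the
  emulated cohort is observational, no inbreeding parameter). Samples
  split 50/50 across two chip designs mirroring the real arrays: the
  quad-like design probes rs1800460, the 550-like design probes neither
  causal SNP; both probe all tags. Genotyping errors flip typed alleles
  independently; switch errors exchange haplotype suffixes at random
  typed positions. Truth is recorded before corruption.
* **Ancestry markers** (`simulate_ancestry_markers()`): the
  Balding–Nichols model — population frequency
  $\sim \mathrm{Beta}\big(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\big)$,
  mean $p$, variance $p(1-p)F$ — with default $F_{ST} = 0.1$, plus a
  labelled reference subset standing in for an external reference panel
  of populations.
* **X markers** (`simulate_x_markers()`): females Binomial(2, p), males
  hemizygous coded diploid-style 0/2 (the common array export
  convention). Genotyping error is a single-allele miscall, which makes
  male X heterozygosity equal the error rate in expectation.

Not emulated: realistic genome-wide LD, recombination maps, real
reference-panel haplotype structure, batch effects, relatedness, or
admixed individuals. Passing tests therefore demonstrate that the
*algorithms* recover the truth under the model's own assumptions; they do
not certify accuracy on real biobank data, where LD structure, panel
mismatch and assay artefacts are harsher. In particular, the published
cohort-level composition (e.g. 72.74% Caucasian ancestry, an average of
174,911 pruned SNPs) depends on the real biobank and is deliberately not
a target of the synthetic runs.

## Numerical and design choices

* Forward–backward in scaled linear space (per-marker renormalization);
  log-space would work equally but the scaled recursion is the reference
  contract here.
* Hard-call ties → no-call; missing genotypes at either causal SNP →
  no-call diplotype; no-calls are excluded from frequency denominators
  and reported in a separate accounting row.
* Percentages are compared at two decimals with a ±0.01 band in the
  tests, because the published tables mix rounding and truncation
  (97.826 printed as 97.82, 99.8275 printed as 99.83).
* One-vs-rest metrics from a confusion matrix with imputed rows and
  observed columns: TP the diagonal cell, FP the remaining row, FN the
  remaining column, TN the rest. This marginal construction is the
  unique one that reproduces all 12 published metric cells from the
  published 3×3 defective-allele matrix. Zero denominators yield
  flagged `NA`s, never silent zeros.
* The two published validation sets (583 genotyping, 59 sequencing
  samples) overlap in 12 samples; merging keeps the sequencing record
  (the stronger gold standard) and errors on any label conflict. The 12
  overlap samples are reconstructed from the imputed-\*1/\*3A,
  observed-\*1/\*3A cell of each table — the only cell large enough in
  both — which is exactly the assignment under which the merged set
  collapses to the published 630-sample matrix.
* The emulated cohort is reported with 87,979 samples throughout; the
  source also prints 89,797 in one place, but 87,979 is the number every
  table sums to.

## Problem sizes used by the test-suite

The suites run end-to-end on deliberately desk-scale problems: panels of
120–2,000 haplotypes, cohorts of 120–600 samples, 400–2,000 ancestry
markers, 200–500 X markers, and 20,000 haplotypes/samples for the
frequency-calibration checks. These sizes keep every property
well-powered (binomial 4-SE bands, ≥99% recovery thresholds) while the
whole suite completes in well under a minute.

```{r pipeline, eval = FALSE}
run <- run_pipeline(tpmt_config(seed = 1, n_samples = 600))
print(run)
summary(run)
```

## Known limitations

* The HMM is a desk-scale stand-in for production imputation tools; it
  uses a constant switch rate, biallelic SNPs only, and no
  surrogate-family state reduction, so it should not be pointed at
  genome-wide panels.
* The info measure's collapse at ultra-rare variants (above) means call
  rates near the QC boundary vary across seeds; this is faithful to how
  the filter behaves, not a defect of the seed.
* Sanger-style validation data are emulated only as label pairs; no
  sequence-level error model is included.
* Indels and multi-allelic sites are out of scope.
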