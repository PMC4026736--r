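# tpmtstar

Identification of TPMT high-risk metabolizer phenotypes from array
genotype data.

Thiopurine drugs (azathioprine, 6-mercaptopurine, thioguanine) are
inactivated by thiopurine methyltransferase (TPMT). Carriers of one or
two defective *TPMT* alleles face severe, potentially lethal
myelosuppression at standard doses, and genotype-based dosing guidelines
exist — but the common GWAS arrays sitting in biobanks probe at most one
of the two SNPs that define the frequent defective alleles. `tpmtstar`
implements the full computational pipeline that closes that gap:

* **Reference-panel imputation** of rs1800460 (C>T) and rs1142345 (T>C)
  with a Li–Stephens-style haplotype-copying HMM: hidden states are the
  panel haplotypes, transitions stay/switch with probability
  `1 − ρ + ρ/K` / `ρ/K`, emissions match the observed allele with
  probability `1 − ε`. Posterior alt probability at marker *m* is
  `Σ_k γ_k(m) h_k(m)`.
* **Quality filtering** by the ratio-of-variances info score,
  `info = 1 − Σ(f_i − e_i²) / (2N θ̂(1−θ̂))` with
  `e_i = p_i1 + 2p_i2`, `f_i = p_i1 + 4p_i2`, retaining variants with
  info ≥ 0.9.
* **Star-allele translation**: haplotypes map to \*1 = (C,T),
  \*3A = (T,C), \*3B = (T,T), \*3C = (C,C); unphased genotypes go
  through a fixed 3×3 lookup in which the double heterozygote resolves
  in cis to \*1/\*3A. Phenotype is trimodal: 0 defective alleles =
  normal, 1 = intermediate, 2 = low activity.
* **Ancestry and sex inference**: LD pruning (r² < 0.2), PCA on
  dosages standardized by `2p̂` and `sqrt(2p̂(1−p̂))`, k-nearest-neighbor
  classification against labelled references, and X-heterozygosity sex
  calls (`F = 1 − obsHet/expHet`; male if F > 0.8, female if F < 0.2).
* **Reporting and validation**: allele/genotype/phenotype frequency
  tables by ancestry group, confusion matrices, concordance, and
  one-vs-rest sensitivity/specificity/PPV/NPV.
* **A synthetic cohort generator** (population-specific star-allele
  frequencies, two chip designs, Balding–Nichols ancestry markers,
  X markers) so the whole pipeline is testable end-to-end against known
  truth, plus the published count tables shipped as plain-text fixtures.

See the vignette (`vignettes/tpmt-imputation.Rmd`) for the models,
parameter defaults and design decisions.

## Worked example

```r
library(tpmtstar)
run <- run_pipeline(tpmt_config(seed = 1, n_samples = 600))
print(run)
```

```
tpmtstar pipeline run (seed 1): 600 samples, 593 called
  ancestry super-group recovery: 100.00%
  sex recovery: 100.00% (0.00% undetermined)
  variants passing info >= 0.90 on quad-like: 12 / 12
  variants passing info >= 0.90 on 550-like: 12 / 12
  diplotype concordance vs truth: 100.00%
  defective-count concordance:    100.00%
```

The run simulates a four-group cohort (600 samples, group sizes
proportional to the emulated biobank), assigns ancestry and sex from
simulated markers, imputes the two causal SNPs per chip design against a
2,000-haplotype reference panel, translates to star diplotypes, and
validates against the simulation truth. 7 of 600 samples end as
no-calls (posterior below the 0.9 call threshold); every called
diplotype matches the truth. The phenotype table for the same run:

```r
print(run$tables$phenotypes)
```

```
phenotypes frequency table
             Caucasian   African     Hispanic   Asian       Total
normal       398 (92.56) 102 (90.27) 34 (87.18) 11 (100.00) 545 (91.91)
intermediate 31 (7.21)   10 (8.85)   5 (12.82)  0 (0.00)    46 (7.76)
low          1 (0.23)    1 (0.88)    0 (0.00)   0 (0.00)    2 (0.34)
no-calls excluded from denominators: Caucasian=6, African=0, Hispanic=0, Asian=1, Total=7
```

Counts are per assigned ancestry group with percentages of called
samples in parentheses — about 8% of samples carry one defective allele
(intermediate metabolizers) and a fraction of a percent carry two, in
line with the configured population frequencies.

A thin command-line wrapper over the same functions is included at
`inst/cli/tpmt.R` (subcommands `run`, `fixtures`, `impute`, `translate`,
`validate`).

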