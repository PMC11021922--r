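# refugiabc

Population-genetic structure and Pleistocene-refugium scenario testing for
coastal seabirds, in R.

Pigeon Guillemots (*Cepphus columba*) and similar nearshore seabirds breed in
small colonies strung along the North Pacific coast. Their mitochondrial
control region (mCR) and nuclear loci often show geographic structure that
could reflect either present-day restricted gene flow (a stepping-stone
pattern, producing isolation by distance) or historical fragmentation into
glacial refugia followed by re-expansion. `refugiabc` implements the full
analysis chain needed to distinguish these hypotheses from sequence and
genotype data:

* **Diversity and neutrality** — haplotype collapsing; Nei's unbiased
  haplotype diversity *h* = *n*/(*n*−1)·(1 − Σp̂ᵢ²); Tajima's nucleotide
  diversity π; Ewens–Watterson and Chakraborty neutrality tests via
  conditional simulation from the Ewens sampling formula (the configuration
  law given the allele count *k* is θ-free, so *F*<sub>exp</sub> = E[Σp̂ᵢ² | *n*, *k*]
  is estimated by Monte Carlo without knowing θ).
* **Structure** — AMOVA Φ<sub>ST</sub> on Kimura 2-parameter distances with
  gamma rate correction (α = 0.42), frequency F<sub>ST</sub> for diploid
  multilocus data, permutation significance with *p* = (*b*+1)/(*B*+1), and
  Benjamini–Yekutieli thresholds for pairwise families.
* **Isolation by distance** — Mantel tests of Slatkin-linearized
  *f*/(1−*f*) against log great-circle distance between location midpoints.
* **Demographic inference** — a structured-coalescent simulator for three
  refugial scenarios (two refugia; single southern refugium with stepwise
  northward colonization; two refugia with secondary-contact admixture),
  HKY+I+G sequence evolution (*I* = 0.796, gamma shape 0.733, mean rate
  6.5×10⁻⁷ /site/generation), and DIYABC-style approximate Bayesian
  computation: a 39-statistic summary vector, rejection on MAD-standardized
  Euclidean distance, multinomial-logistic posterior scenario probabilities,
  and Type I/II error validation with pseudo-observed datasets.
* **Synthetic data** — a generator reproducing the study's sampling design
  (202 mtDNA / 194 nuclear samples, 22 sites, 11 locations, 3 regions) under
  any scenario, plus Wright–Fisher stepping-stone and island fixtures for
  validating the IBD machinery.

## Worked example

```r
library(refugiabc)

# a study-shaped dataset simulated under scenario 1 (two refugia)
bundle <- generate_study(scenario_id = 1, seed = 42, dir = "demo")
aln <- bundle$alignment

collapse_haplotypes(aln)
#> haplotype_table: 98 haplotypes in 202 samples; counts: 22 12 10 7 6 ...

round(haplotype_diversity(collapse_haplotypes(aln)), 3)   #> 0.977
round(100 * nucleotide_diversity(aln), 3)                 #> 2.258  (pi as %)

amova(aln, bundle$partition, level = "region",
      spec = distance_spec("K2P-gamma", 0.42), n_perm = 999, seed = 1)
#> Phi_ST = 0.2690 (sigma_a = 0.003719, sigma_w = 0.01011), p = 0.001 [999 perms]

# Ewens-Watterson expected homozygosity for n = 29 sequences, 14 haplotypes
ewens_watterson(n = 29, k = 14, n_draws = 1e5, seed = 1)
#> Ewens-Watterson test (n = 29)
#>   k = 14; F_exp = 0.1163 (sd 0.0229); ...
```

The Φ<sub>ST</sub> of 0.27 (p = 0.001) says 27% of the squared-distance
variation in this simulated dataset lies among the three regions — the
deep-split signature scenario 1 is built to produce. The conditional
expectation 0.116 is what a neutral sample of 29 with 14 haplotypes should
show for homozygosity; comparing an observed Σp̂ᵢ² against it is the
Ewens–Watterson test.

End-to-end pipelines (`run_observed()`, `run_abc()`) and a CLI
(`inst/cli/refugiabc`, subcommands `simulate-study`, `sumstats`, `amova`,
`neutrality`, `mantel`, `abc-build`, `abc-choose`, `abc-validate`,
`run-all`) orchestrate the same steps from a JSON config, writing
seed-stamped TSV reports.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
models, the coalescent and mutation machinery, every tunable default and the
reasoning behind it, and what the synthetic-data tests do and do not
establish.
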