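# sdrsurv

Survival Dimensionality Reduction (SDR) for candidate-SNP cohorts:
gene–gene interaction analysis of right-censored survival data.

## The problem

Candidate-gene survival studies genotype a small panel of SNPs (here, four
*VEGFR-2* and two *P2X7R* polymorphisms in a metastatic prostate cancer
cohort) and ask whether genotypes predict overall survival. Single-SNP Cox
regression often finds nothing, yet a *combination* of genotypes may still
separate prognosis — statistical epistasis. `sdrsurv` implements the full
analysis chain for this design:

- **Panel QC** — allele frequencies, exact conditional and χ² Hardy–Weinberg
  tests, pairwise LD (D′, r²) and EM haplotype frequencies from unphased
  genotypes.
- **Per-SNP association** — Cox proportional hazards (Efron ties) under
  additive, dominant and recessive codings with a panel-size Bonferroni
  threshold (0.05/6 = 0.0083 for a six-SNP panel).
- **SDR engine** — for every k-way SNP subset, subjects partition into ≤ 3^k
  multilocus genotype cells; each cell is labeled *favorable* or
  *unfavorable* by the sign of its log-rank observed−expected deaths against
  the training sample; a subject's predicted survival curve is their profile
  group's training Kaplan–Meier curve; models are ranked by cross-validated
  IPCW **Integrated Brier Score**

  BS(t) = n⁻¹ Σᵢ [ 1{Tᵢ ≤ t, δᵢ = 1} Sᵢ(t)² / G(Tᵢ⁻) + 1{Tᵢ > t}(1 − Sᵢ(t))² / G(t) ],
  IBS = τ⁻¹ ∫₀^τ BS(t) dt

  with censoring distribution G and bound τ taken from the training fold
  only; the minimum mean testing IBS selects the model, and a permutation
  test (re-running the full search per permutation) certifies it.
- **Synthetic cohorts** — seeded generator of HWE genotypes at configurable
  MAFs with a planted genotype-profile survival effect, so the whole
  pipeline is testable without patient data.

## Worked example

The published panel QC is reproducible exactly from the printed genotype
tallies:

```r
library(sdrsurv)
st <- study_snp_table()
gm <- genotypes_from_counts(attr(st, "panel"), st)
popgen_table(gm)[, c("snp_id", "gene", "freq_major", "hwe_p_exact")]
#>       snp_id    gene freq_major hwe_p_exact
#> 1  rs2071559 VEGFR-2      0.535  0.84352762
#> 2  rs2305948 VEGFR-2      0.940  0.29555658
#> 3  rs1870377 VEGFR-2      0.845  0.69897430
#> 4 rs11133360 VEGFR-2      0.550  1.00000000
#> 5  rs3751143   P2X7R      0.750  0.05885815
#> 6   rs208294   P2X7R      0.530  0.69263369
```

The major-allele frequencies and HWE p-values match the published panel
table to printed precision (0.8435, 0.2956, 0.7, 1, 0.0589, 0.6926).

A full SDR analysis on a synthetic cohort emulating the study conditions
(n = 100, planted 4-way profile, favorable hazard ratio 0.29, >80% events):

```r
cohort <- gen_cohort(synthetic_config(seed = 7))
plan <- cv_plan(cohort$outcome, folds = 10, seed = 7)
search <- sdr_search(cohort$gm, cohort$outcome, 1:4, plan)
search
#> SDR search: 56 subset evaluations
#> per-k best models:
#>  k                                  subset train_ibs  test_ibs
#>  1                               rs2071559 0.1624071 0.1678598
#>  2                     rs2071559+rs2305948 0.1624058 0.1701383
#>  3          rs2071559+rs1870377+rs11133360 0.1527808 0.1634713
#>  4 rs2071559+rs2305948+rs11133360+rs208294 0.1308812 0.1630303
#> selected: rs2071559+rs2305948+rs11133360+rs208294 (k = 4, testing IBS = 0.1630)

perm <- permutation_test(cohort$gm, cohort$outcome, k = search$best$k,
                         plan, B = 199, seed = 8)
perm$p
#> [1] 0.01

lab <- search$labels
fav <- cohort$outcome[!is.na(lab) & lab == "favorable", ]
class(fav) <- class(cohort$outcome)
kaplan_meier(fav)
#> Kaplan-Meier estimate: 46 subjects, 33 events
#> median 207.5 months (95% CI 133.3 - 369.7)
```

Reading the output: all 56 subsets (C(6,k), k = 1..4) were scored; the
4-way model has the lowest cross-validated testing IBS (0.1630) and is
selected. At n = 100 the selected subset overlaps but need not equal the
planted four SNPs (here three of four, plus one null SNP) — the expected
behavior at this sample size with a profile-level effect. The permutation
p of 0.01 (B = 199) says at most one permuted cohort produced as strong a
favorable/unfavorable log-rank separation as the observed model, search
included. The full-data profile labels then feed Kaplan–Meier medians by
profile (favorable 207.5 vs unfavorable 57.05 months in this cohort) and
an adjusted Cox model; `run_pipeline()` chains every stage and writes all
report tables as TSV + JSON.

## Command line

```sh
Rscript inst/scripts/sdr-pipeline.R simulate --outdir fixtures
Rscript inst/scripts/sdr-pipeline.R sdr --genotypes fixtures/genotypes.tsv \
    --survival fixtures/survival.tsv --kmin 1 --kmax 4 --folds 10 \
    --permutations 1000 --seed 42 --outdir reports
```

Exit codes: 0 ok, 2 validation error, 3 convergence/degenerate model.

See `vignettes/sdr-methods.Rmd` for the model details, design decisions
and known limitations.
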