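# gat1map

Structure → function → phenotype analysis for missense variants in the
GABA transporter GAT1 (*SLC6A1*), as a reusable R package plus a small
set of analysis drivers.

*SLC6A1* variants impair GABA reuptake and cause epilepsy and
neurodevelopmental disorders of very variable severity. `gat1map`
relates three layers of evidence on the transporter's 3D structure:

* **Spatial metrics** — for each residue of a PDB structure with a
  bound ligand: the minimum all-atom distance to the ligand
  `min(d(a, b))` over residue atoms `a` and ligand atoms `b`, the
  distance to the transporter axis (principal axis of the TM-segment
  Cα's), distances to the TM1/TM6 helices, and a neighbourhood score —
  the mean functional activity of all scored residues within 5 Å.
* **Cohort statistics** — GABA-uptake activity banded at 10 % and
  42.8 % of wild type (`complete_lof` / `moderate_lof` /
  `wildtype_like`); per-domain activity summaries; patient-versus-
  population domain enrichment and severity-by-activity association as
  exact 2×2 tests reporting both the cross-product and
  conditional-MLE odds ratios with exact CIs; two-tailed Wilcoxon
  rank-sum distance comparisons with Bonferroni correction, with and
  without glycine/proline "helix-breaker" sites.
* **Allele-frequency filter** — the maximum credible population
  allele frequency, prevalence × allelic heterogeneity × genetic
  heterogeneity / (2 × penetrance), and its application to population
  variant tables.

A fully deterministic synthetic-data generator (toy helix bundles in
PDB format plus variant/functional/phenotype tables with planted
associations) makes the entire pipeline testable end to end without any
downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data:

```sh
Rscript analysis/01_simulate.R      # writes results/sim/
Rscript analysis/02_run_pipeline.R  # writes results/report/
Rscript analysis/03_credible_af.R   # writes results/credible_af.json
```

`02_run_pipeline.R` prints, among other blocks:

```
ligand distance by activity group (means, A):
       group_a       group_b mean_a mean_b        p p_bonferroni
1 complete_lof  moderate_lof   9.02   10.8 2.52e-02     7.57e-02
2 complete_lof wildtype_like   9.02   14.7 1.39e-06     4.16e-06
3 moderate_lof wildtype_like  10.76   14.7 6.69e-07     2.01e-06

domain enrichment (patient vs population, unique variants):
      domain odds_ratio_cmle ci_low ci_high p_bonferroni
1      TM1/6           4.430 1.8840   10.93      0.00174
...

severity by activity:
                     severe non_severe
complete_lof              7          5
moderate_or_wildtype      8         40
OR (sample) 7 | OR (CMLE) 6.7 [1.43, 34.8] | p = 0.00636
```

Reading: variants with nearly complete loss of uptake sit closest to
the ligand (9.0 Å versus 14.7 Å for wild-type-like variants; Bonferroni
p = 4.2 × 10⁻⁶), the core `TM1/6` domain — where the generator planted
an 8-fold concentration — is enriched for patient variants, and
complete-LoF carriers are enriched for severe disease (planted odds
ratio ≈ 4.6; this replicate recovers 6.7 with a wide exact CI, as
expected at 60 patients). `03_credible_af.R` prints:

```
prevalence: 161.38 per 100,000 (1 in 619.6)
allelic heterogeneity: 0.06 (11/172)
maximum credible population AF: 6.05e-05
```

Equivalent calls in R:

```r
library(gat1map)
cfg <- sim_config(seed = 2026)
write_simulated_cohort(cfg, "results/sim")
report <- run_analysis(list(
  structure  = list(path = "results/sim/structure.pdb",
                    chain = "A", ligand_code = "LIG"),
  segments   = list(tm1 = "1-20", tm6 = "21-40"),
  variants   = list(path = "results/sim/variants.tsv"),
  phenotypes = list(path = "results/sim/phenotypes.tsv"),
  domain_map = list(path = "results/sim/domain_map.tsv"),
  af = list(incidence_per_100k = 2.65, duration_years = 60.9,
            allelic_het = 0.06, penetrance = 0.8)))
report$severity
```

## Layout

```
R/                  package code (structure I/O, spatial metrics,
                    cohort modelling, statistics, AF filter,
                    synthetic data, pipeline orchestration)
analysis/           numbered narrative drivers over the package
scripts/            acceptance script
tests/testthat/     unit, property and study-level tests
vignettes/          methods and design notes
inst/extdata/       approximate (synthetic) GAT1 domain map
```
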