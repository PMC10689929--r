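---
title: "Mapping transporter variants in 3D: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transporter variants in 3D: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gat1map)
```

## The problem

Missense variants in *SLC6A1* impair GAT1, the GABA transporter that
clears GABA from inhibitory synapses, and cause a spectrum of epilepsy
and neurodevelopmental phenotypes. Three layers of evidence can be
related through the protein's 3D structure:

1. **Position → pathogenicity.** Are patient variants concentrated in
   particular structural domains compared with general-population
   variants?
2. **Position → function.** Do variants close to the ligand-binding
   site (and to the transporter axis, and to the TM1/TM6 helices) lose
   more GABA-uptake activity *in vitro*?
3. **Function → phenotype.** Do carriers of variants with nearly
   complete loss of uptake have more severe disease?

`gat1map` implements each layer as plain functions over three inputs: a
PDB structure with a bound ligand, protein-level variant tables with
optional uptake readouts, and patient phenotype tables.

## Spatial metrics

All metrics operate on heavy atoms; hydrogens are kept in the model but
excluded from distances by default, because experimental transporter
structures rarely resolve them and protonation should not move a
distance. Alternate conformations collapse to the first listed one so
every quantity is deterministic.

* **Ligand distance** `min_distance_to_ligand()`: minimum Euclidean
  distance over all (residue atom, ligand atom) pairs, in Å. With no
  GABA in the deposition, the bound inhibitor at the GABA site is the
  reference group.
* **Axis distance** `distance_to_axis()`: a membrane transporter has a
  natural vertical axis, but a deposition does not annotate one. The
  default construction (`fit_axis()`, mode
  `principal_axis_of_segment_CA`) takes the first principal direction
  of the Cα coordinates of the designated TM segments, anchored at
  their centroid — structure-intrinsic and reproducible. A `fixed_z`
  mode serves membrane-oriented depositions. The direction's sign is
  normalized; point-to-line distances are sign-free anyway.
* **Segment distance** `distance_to_segment()`: minimum heavy-atom
  distance to a residue set (TM1, TM6); membership gives 0.
* **Neighbourhood score** `neighborhood_score()`: per-residue
  functional activity averaged over all scored residues within a
  radius, default 5 Å, read inclusively (≤ 5.0). Two open choices are
  config switches rather than silent assumptions: the proximity
  criterion (`all_heavy`, matching the all-atom ligand-distance
  convention, versus `ca_only`) and whether the query residue's own
  score joins the average (`include_self`, default yes — a singleton
  residue then reports its own score).

Positions absent from the model (structures routinely lack termini) are
*unresolved*: lookups return `NULL`, metrics return `NA`, records are
excluded from spatial analyses and each exclusion is listed in the run
log. This keeps curation auditable without crashing on the common case.

## Cohort modelling

* **Activity groups.** Mean GABA uptake as % of wild type is banded
  into `complete_lof` (< 10), `moderate_lof` (10–42.8) and
  `wildtype_like` (> 42.8). The 42.8 % threshold is the empirical
  boundary below which benign-like control variants do not fall in the
  underlying assay work. Band edges are lower-inclusive and
  42.8-inclusive for the moderate band; the convention is stated here
  once and applied everywhere, including the "below threshold" counts
  of `domain_activity_summary()` (42.8 counts as low).
* **Severity.** Epilepsy syndromes harmonized to twelve labels are
  binarized: DEE, EMAS, LGS and intractable absence epilepsy are
  severe; no seizures, CAE, unclassified epilepsy, generalized
  epilepsy, GGE, TLE and NAFE are non-severe; everything else —
  including missing data and intractable primary generalized epilepsy,
  for which a defensible binary call does not exist — is `other` and is
  excluded (with a reported count) from the contingency analysis. The
  mapping is total and idempotent, and the dictionaries are arguments,
  not constants.
* **Domains.** A residue→domain map is a set of validated 1-based,
  inclusive, non-overlapping intervals supplied as data. The shipped
  `default_gat1_domain_map()` is an *approximate, synthetic* stand-in
  assembled from public topology annotations, intended for
  demonstration; serious use should supply a curated map. Tests never
  rely on it.
* **Counting levels.** Domain enrichment is computed at the
  unique-variant level (a recurrent variant counts once); severity at
  the patient level (every carrier counts). The level is an explicit
  parameter because mixing them silently is the easiest way to get
  these analyses wrong.
* **Helix breakers.** Glycine and proline disrupt helical geometry, so
  substitutions at such residues can act through backbone distortion
  rather than position per se. The distance comparisons are therefore
  reported both with and without them (`gly_pro_filter()`), which
  changes sample composition but never group membership.

## Statistics

2×2 tables go through the exact conditional test; the two-sided p-value
follows the point-probability convention. Because the literature rarely
states which odds-ratio flavour a "fold enrichment" is, both the sample
(cross-product) estimate — with the Haldane–Anscombe 0.5 correction
when a cell is zero — and the conditional-MLE estimate with its exact
95 % CI are always reported side by side. Rank comparisons use the
two-tailed Wilcoxon rank-sum test, exact by enumeration for tie-free
pooled samples of ≤ 20, otherwise the mid-rank normal approximation
with tie and continuity corrections. Multiplicity is Bonferroni, with
the multiplier logged: 3 for the pairwise activity-group comparisons,
the number of domains for enrichment.

## The credible allele-frequency filter

For a dominant disorder, a pathogenic variant's population allele
frequency cannot credibly exceed

$$\mathrm{AF}_{\max} \;=\; \frac{\text{prevalence} \times
\text{allelic het.} \times \text{genetic het.}}{2 \times
\text{penetrance}},$$

with prevalence approximated as incidence × mean disease duration and
the division by two converting affected individuals to alleles. With
incidence 2.65 per 100,000 live births, duration 60.9 years (prevalence
161.38/100,000 ≈ 1/619.6), allelic heterogeneity 0.06 (most frequent
variant in 11 of 172 patients, rounded to the 2-decimal working
precision such calculators use), genetic heterogeneity 1 and penetrance
0.8, the cutoff is 6.05 × 10⁻⁵. Population variants at or below the
cutoff remain compatible with pathogenicity (`af_filter()` uses ≤).

```{r af}
prev <- prevalence_from_incidence(2.65, 60.9)
signif(max_credible_af(prevalence = prev$proportion, allelic_het = 0.06,
                       genetic_het = 1, penetrance = 0.8), 3)
```

## The synthetic generator

`make_helix_bundle()` builds an idealized bundle — backbone-only
(N, Cα, C, O) α-helices with 1.5 Å rise and 100° twist per residue,
standing on a circle around a one-atom ligand — and
`simulate_cohort()` draws variant, functional and phenotype tables on
it. The generator's defaults define the simulated study conditions and
were fixed once:

* geometry: 6 helices × 20 residues on a 10 Å circle, so residues span
  roughly 7–20 Å of ligand distance;
* activity: 100 · logistic((d − 13)/2) plus Gaussian noise (sd 10
  percentage points), truncated at 0 — midpoint and scale sit inside
  the distance range so all three activity bands are populated, the
  way the real assay data populate them;
* patient positions 8-fold over-weighted in the core `TM1/6` domain
  against a uniform population background, matching the magnitude of
  domain enrichment such cohorts show;
* severity Bernoulli rates 0.55 (complete LoF) versus 0.21 (others), a
  planted odds ratio of ≈ 4.6, the reported effect size for this
  association.

Randomness is fully seeded and partitioned per table, so growing the
population table does not perturb the patient table, and identical
configurations are byte-identical on disk.

What the generator does *not* emulate: GAT1's real fold and side
chains, the empirical (non-logistic) activity distribution, trafficking
defects that reduce activity without spatial proximity, recurrent
variants, and missing/heterogeneous clinical ascertainment. Passing the
simulation-recovery tests therefore shows the pipeline detects the
planted statistical structure at realistic sizes — not that real
cohorts satisfy these models.

## Problem sizes and numerical choices

The test-suite simulations use cohorts of 25–600 variants on bundles of
up to 120 residues, 150–400 replicates for recovery checks and 2,000
replicates for null error rates; these sizes make the planted effects
detectable with comfortable margins while keeping the suite quick.
Exactness checks are exhaustive where the domain is small (all 2×2
tables with total ≤ 40 against hypergeometric enumeration; all rank-sum
cases with pooled n ≤ 12 against permutation enumeration). Distances
are validated against brute-force pairwise oracles to 1e-6 Å and under
random rigid motions. Degenerate inputs fail loudly and early: zero
margins, overlapping domain intervals, empty segments, negative
activities and out-of-range frequencies are errors, not warnings.

## Known limitations

* One chain and one ligand copy per run; multimeric depositions need an
  explicit selection.
* Protein-level variants only: no VCF lifting, no VEP, no ACMG logic.
* The axis and the 5 Å neighbourhood criterion are reasonable
  constructions, not community standards; both are configurable and
  recorded in every report.
* The shipped GAT1 domain map is approximate (see above).
* Trafficking-defective variants can lose activity far from the
  ligand; position-based metrics cannot see this mechanism.
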