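# Maximum credible population allele frequency: the highest allele
# frequency in a reference population compatible with pathogenicity for a
# disease of given prevalence, heterogeneity and penetrance, plus the
# filter applying it and patient/population overlap accounting.

#' Disease prevalence from incidence and duration
#'
#' Point prevalence approximated as incidence times mean disease duration.
#' Both the per-100,000 scale used in the epidemiological literature and
#' the plain proportion are returned so no caller has to rescale.
#'
#' @param incidence_per_100k Cases per 100,000 live births (> 0).
#' @param duration_years Mean disease duration in years (> 0).
#' @return List with `per_100k`, `proportion` and `one_in` (the "1 in N"
#'   form, N = 1/proportion).
#' @export
prevalence_from_incidence <- function(incidence_per_100k, duration_years) {
  if (incidence_per_100k <= 0 || duration_years <= 0) {
    stop("incidence and duration must be positive", call. = FALSE)
  }
  per_100k <- incidence_per_100k * duration_years
  list(per_100k = per_100k,
       proportion = per_100k / 1e5,
       one_in = 1e5 / per_100k)
}

#' Maximum credible population allele frequency
#'
#' For a dominant disorder, the allele frequency of a pathogenic variant
#' in the general population cannot exceed
#' `prevalence * allelic_het * genetic_het / (2 * penetrance)`:
#' disease prevalence (as a proportion of individuals) capped by the
#' largest share any one gene (`genetic_het`) and any one variant within
#' the gene (`allelic_het`) contributes, divided by twice the penetrance
#' to convert affected individuals to alleles. Population variants above
#' the cutoff are too common to be credibly causal at the assumed
#' penetrance.
#'
#' @param prevalence Disease prevalence as a proportion (e.g. 1.6138e-3),
#'   or use `incidence_per_100k` + `duration_years` instead.
#' @param allelic_het Maximum allelic contribution, in (0, 1].
#' @param genetic_het Maximum genetic contribution, in (0, 1]; 1 when the
#'   disorder is defined by variants in a single gene.
#' @param penetrance Variant penetrance, in (0, 1].
#' @param incidence_per_100k,duration_years Optional alternative to
#'   `prevalence`, combined via [prevalence_from_incidence()].
#' @return Allele frequency (proportion).
#' @export
max_credible_af <- function(prevalence = NULL, allelic_het, genetic_het = 1,
                            penetrance,
                            incidence_per_100k = NULL,
                            duration_years = NULL) {
  if (is.null(prevalence)) {
    if (is.null(incidence_per_100k) || is.null(duration_years)) {
      stop("supply either prevalence or incidence_per_100k + duration_years",
           call. = FALSE)
    }
    prevalence <- prevalence_from_incidence(incidence_per_100k,
                                            duration_years)$proportion
  }
  if (prevalence <= 0) stop("prevalence must be positive", call. = FALSE)
  if (allelic_het <= 0 || allelic_het > 1 ||
      genetic_het <= 0 || genetic_het > 1) {
    stop("heterogeneity parameters must lie in (0, 1]", call. = FALSE)
  }
  if (penetrance <= 0 || penetrance > 1) {
    stop("penetrance must lie in (0, 1]", call. = FALSE)
  }
  prevalence * allelic_het * genetic_het / (2 * penetrance)
}

#' Estimate maximum allelic contribution from a cohort
#'
#' The share of the cohort attributable to the most frequent single
#' variant, rounded to the working precision used for the allele-frequency
#' calculation (2 decimal places by default, matching how such parameters
#' are entered in allele-frequency calculators).
#'
#' @param n_top_variant Carriers of the most frequent variant.
#' @param n_cohort Cohort size.
#' @param digits Rounding for the reported value; `Inf` for no rounding.
#' @return Allelic heterogeneity estimate.
#' @export
estimate_allelic_het <- function(n_top_variant, n_cohort, digits = 2) {
  stopifnot(n_top_variant >= 0, n_cohort > 0, n_top_variant <= n_cohort)
  x <- n_top_variant / n_cohort
  if (is.finite(digits)) round(x, digits) else x
}

#' Filter population variants on the credible-frequency cutoff
#'
#' A variant passes (remains compatible with pathogenicity) when its
#' observed allele frequency is at or below the cutoff; strictly above
#' means too common.
#'
#' @param variants Data frame with an `allele_frequency` column in [0, 1].
#' @param cutoff Maximum credible allele frequency.
#' @return List with `pass` and `fail` tibbles; an exact partition.
#' @export
af_filter <- function(variants, cutoff) {
  af <- variants$allele_frequency
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  over <- !is.na(af) & af > cutoff
  list(pass = variants[!over, , drop = FALSE],
       fail = variants[over, , drop = FALSE])
}

#' Overlap between patient and population variant sets
#'
#' Variant identity is the protein-level triple (pos, ref_aa, alt_aa).
#'
#' @param patient_variants,population_variants Data frames with columns
#'   `pos`, `ref_aa`, `alt_aa`.
#' @return List with `n_patient` (unique patient variants), `n_overlap`,
#'   `fraction` (share of the patient set also seen in the population
#'   set) and the overlapping keys.
#' @export
overlap_report <- function(patient_variants, population_variants) {
  key <- function(v) unique(paste(v$pos, v$ref_aa, v$alt_aa, sep = "|"))
  pk <- key(patient_variants)
  gk <- key(population_variants)
  ov <- intersect(pk, gk)
  list(n_patient = length(pk),
       n_overlap = length(ov),
       fraction = if (length(pk)) length(ov) / length(pk) else 0,
       overlap_keys = ov)
}
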