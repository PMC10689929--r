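# End-to-end orchestration: structure parsing, spatial metrics, activity
# stratification, domain summaries and enrichment, distance-vs-activity
# comparisons (with and without helix-breaker exclusion), patient-level
# severity contingency, and the allele-frequency block — one config in,
# one report out.

.parse_segment <- function(x) {
  # accepts an integer vector, or strings like "5-20" / c("5-20", "40-55")
  if (is.numeric(x)) return(as.integer(x))
  unlist(lapply(x, function(s) {
    if (grepl("^[0-9]+-[0-9]+$", s)) {
      ab <- as.integer(strsplit(s, "-")[[1]])
      seq.int(ab[1], ab[2])
    } else as.integer(s)
  }))
}

#' Run the full structure-function-phenotype analysis
#'
#' Executes, in order: structure parsing, per-residue spatial metrics
#' (ligand distance, axis distance, TM1/TM6 distances, neighbourhood
#' score), activity-group stratification, per-domain activity summary,
#' domain enrichment of patient versus population variants (unique-variant
#' level), pairwise Wilcoxon distance comparisons across activity groups
#' for every metric with Bonferroni correction — with and without
#' glycine/proline wild-type residues — the patient-level
#' severity-by-activity contingency test, and the maximum credible
#' allele-frequency block with patient/population overlap accounting.
#'
#' @param config A list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{structure}{`path`, `chain`, `ligand_code`.}
#'   \item{segments}{`tm1`, `tm6`: residue numbers or `"start-end"`
#'     strings.}
#'   \item{variants}{`path`: variant table (see [read_variant_table()])
#'     with a `source` column (`patient` / `population` / `vus`).}
#'   \item{phenotypes}{optional `path`: patient table (see
#'     [read_phenotype_table()]).}
#'   \item{domain_map}{`path`: TSV interval map.}
#'   \item{thresholds}{optional: `lof` (42.8), `complete` (10),
#'     `radius` (5), `bonferroni_m` (3).}
#'   \item{af}{optional: `incidence_per_100k`, `duration_years` (or
#'     `prevalence` as a proportion), `allelic_het` (omit to estimate
#'     from the phenotype table), `genetic_het`, `penetrance`.}
#' }
#' @return A list of class `analysis_report` with elements `meta`,
#'   `per_residue`, `per_variant`, `domain_summary`, `enrichment`,
#'   `comparisons`, `severity`, `af` and `log` (character vector
#'   narrating the n at every stage and every excluded record).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))

  th <- config$thresholds
  lof <- th$lof %||% 42.8
  complete <- th$complete %||% 10
  radius <- th$radius %||% 5
  m_bonf <- th$bonferroni_m %||% 3

  ps <- parse_structure(config$structure$path, config$structure$chain,
                        config$structure$ligand_code)
  say("structure: ", ps$source_id, ", ",
      length(resolved_positions(ps)), " resolved residues")

  tm1 <- .parse_segment(config$segments$tm1)
  tm6 <- .parse_segment(config$segments$tm6)
  dmap <- read_domain_map(config$domain_map$path)

  variants <- read_variant_table(config$variants$path)
  bad <- variants[!variants$parse_ok, , drop = FALSE]
  for (b in bad$id) say("WARN unparsable variant record: ", b)
  variants <- variants[variants$parse_ok, , drop = FALSE]
  variants$activity_pct <- if ("activity_pct" %in% names(variants))
    variants$activity_pct else NA_real_
  variants$domain <- assign_domain(variants$pos, dmap)
  variants$activity_group <- classify_activity_group(
    variants$activity_pct, lof_threshold = lof,
    complete_threshold = complete)

  is_missense <- variants$consequence == "missense"
  resolved <- variants$pos %in% resolved_positions(ps)
  n_unresolved <- sum(is_missense & !resolved)
  for (i in which(is_missense & !resolved)) {
    say("WARN unresolved position, excluded from spatial metrics: ",
        variants$id[i], " (pos ", variants$pos[i], ")")
  }
  say("variants: ", nrow(variants), " total; ", sum(is_missense),
      " missense (", sum(is_missense & resolved), " resolved, ",
      n_unresolved, " unresolved); ", sum(!is_missense), " non-missense")

  # per-residue activity map: mean over scored missense variants at a site
  scored <- variants[is_missense & !is.na(variants$activity_pct), ,
                     drop = FALSE]
  scores <- tapply(scored$activity_pct, scored$pos, mean)
  scores <- stats::setNames(as.numeric(scores), names(scores))

  axis <- fit_axis(ps, segment = union(tm1, tm6))
  per_residue <- residue_metrics(ps, tm1 = tm1, tm6 = tm6,
                                 scores = scores, axis = axis,
                                 radius = radius)

  mcols <- c("d_ligand", "d_axis", "d_tm1", "d_tm6", "neighborhood_score")
  per_variant <- dplyr::left_join(
    variants[setdiff(names(variants), mcols)],
    per_residue[c("seq_num", mcols)],
    by = c(pos = "seq_num"))
  per_variant$resolved <- per_variant$pos %in% resolved_positions(ps) &
    per_variant$consequence == "missense"
  per_variant[which(per_variant$consequence != "missense"), mcols] <- NA_real_

  domain_summary <- domain_activity_summary(
    scored, dmap, lof_threshold = lof)

  pat <- per_variant[per_variant$source == "patient" & is_missense, ,
                     drop = FALSE]
  pop <- per_variant[per_variant$source == "population", , drop = FALSE]
  enrichment <- if (nrow(pat) && nrow(pop)) {
    domain_enrichment(pat, pop, dmap, level = "unique_variant")
  } else {
    say("enrichment: not computed (missing patient or population set)")
    NULL
  }

  spat <- per_variant[per_variant$resolved &
                        !is.na(per_variant$activity_group), , drop = FALSE]
  gp <- gly_pro_filter(spat)
  say("gly/pro subanalysis: ", nrow(gp$removed),
      " helix-breaker variants removed, ", nrow(gp$kept), " kept")
  comparisons <- dplyr::bind_rows(lapply(
    c("d_ligand", "d_axis", "d_tm1", "d_tm6"), function(mt) {
      dplyr::bind_rows(
        dplyr::mutate(distance_group_comparison(spat, mt, m = m_bonf),
                      subset = "all"),
        dplyr::mutate(distance_group_comparison(gp$kept, mt, m = m_bonf),
                      subset = "gly_pro_removed"))
    }))

  phen <- if (!is.null(config$phenotypes$path) &&
              file.exists(config$phenotypes$path)) {
    read_phenotype_table(config$phenotypes$path)
  } else NULL
  severity <- if (is.null(phen) || nrow(phen) == 0L) {
    say("severity block: not computed (no phenotype records)")
    "not computed"
  } else {
    joined <- dplyr::left_join(
      phen, per_variant[c("id", "activity_group")],
      by = c(variant_id = "id"))
    res <- severity_by_activity(joined)
    say("severity block: ", sum(res$table), " patients analysed, ",
        res$n_excluded_other, " 'other' excluded, ",
        res$n_excluded_unscored, " without scored variant excluded")
    res
  }

  af <- if (!is.null(config$af)) {
    a <- config$af
    prev <- if (!is.null(a$prevalence)) {
      list(proportion = a$prevalence, per_100k = a$prevalence * 1e5,
           one_in = 1 / a$prevalence)
    } else {
      prevalence_from_incidence(a$incidence_per_100k, a$duration_years)
    }
    ah <- a$allelic_het
    if (is.null(ah) && !is.null(phen)) {
      tab <- table(phen$variant_id)
      ah <- estimate_allelic_het(max(tab), nrow(phen))
      say("allelic heterogeneity estimated from cohort: ", ah)
    }
    cutoff <- max_credible_af(prevalence = prev$proportion,
                              allelic_het = ah,
                              genetic_het = a$genetic_het %||% 1,
                              penetrance = a$penetrance)
    ov <- overlap_report(per_variant[per_variant$source == "patient", ],
                         pop)
    filt <- if ("allele_frequency" %in% names(pop) &&
                any(!is.na(pop$allele_frequency))) {
      f <- af_filter(pop, cutoff)
      list(n_pass = nrow(f$pass), n_fail = nrow(f$fail))
    } else NULL
    say("AF block: cutoff ", signif(cutoff, 3), "; overlap ",
        ov$n_overlap, "/", ov$n_patient)
    list(prevalence = prev, allelic_het = ah,
         genetic_het = a$genetic_het %||% 1, penetrance = a$penetrance,
         cutoff = cutoff, overlap = ov[c("n_patient", "n_overlap",
                                         "fraction")],
         filter = filt)
  } else NULL

  meta <- list(
    n_input = nrow(variants) + nrow(bad),
    n_unparsable = nrow(bad),
    n_missense_spatial = sum(is_missense & resolved),
    n_unresolved = n_unresolved,
    n_non_missense = sum(!is_missense),
    thresholds = list(lof = lof, complete = complete, radius = radius,
                      bonferroni_m = m_bonf)
  )
  say("reconciliation: ", meta$n_missense_spatial, " spatial + ",
      meta$n_unresolved, " unresolved + ", meta$n_non_missense,
      " non-missense + ", meta$n_unparsable, " unparsable = ",
      meta$n_input, " input records")

  structure(list(meta = meta, per_residue = per_residue,
                 per_variant = per_variant,
                 domain_summary = domain_summary,
                 enrichment = enrichment, comparisons = comparisons,
                 severity = severity, af = af, log = log),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (everything except the bulk tables), plus
#' `per_residue.tsv`, `per_variant.tsv`, `domain_summary.tsv`,
#' `enrichment.tsv` and `comparisons.tsv`. Regenerating from identical
#' inputs yields identical files.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num_round <- function(df) {
    df[] <- lapply(df, function(c) if (is.numeric(c)) round(c, 6) else c)
    df
  }
  readr::write_tsv(num_round(report$per_residue),
                   file.path(dir, "per_residue.tsv"))
  readr::write_tsv(num_round(report$per_variant),
                   file.path(dir, "per_variant.tsv"))
  readr::write_tsv(num_round(report$domain_summary),
                   file.path(dir, "domain_summary.tsv"))
  if (!is.null(report$enrichment)) {
    readr::write_tsv(num_round(report$enrichment),
                     file.path(dir, "enrichment.tsv"))
  }
  readr::write_tsv(num_round(report$comparisons),
                   file.path(dir, "comparisons.tsv"))
  sev <- report$severity
  json <- list(
    meta = report$meta,
    domain_summary = report$domain_summary,
    severity = if (inherits(sev, "contingency_result")) {
      list(table = as.vector(sev$table),
           odds_ratio_sample = sev$odds_ratio_sample,
           odds_ratio_cmle = sev$odds_ratio_cmle,
           ci = c(sev$ci_low, sev$ci_high), p = sev$p_two_sided,
           n_excluded_other = sev$n_excluded_other,
           n_excluded_unscored = sev$n_excluded_unscored)
    } else sev,
    af = report$af,
    log = report$log
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
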