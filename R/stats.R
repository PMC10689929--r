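# Statistical engines: exact 2x2 enrichment (Fisher), two-tailed
# Wilcoxon rank-sum comparisons with Bonferroni correction, and the two
# study-specific contingency constructions (severity-by-activity and
# per-domain patient-vs-population enrichment).

#' Exact 2x2 enrichment test
#'
#' Wraps the exact conditional test for a 2x2 table. The two-sided p-value
#' follows the point-probability convention (sum of hypergeometric
#' probabilities of tables, at fixed margins, no more likely than the
#' observed one). Two odds-ratio flavours are reported: the sample
#' (cross-product) estimate, with the Haldane--Anscombe 0.5 correction
#' applied to every cell when any cell is zero, and the conditional
#' maximum-likelihood estimate with its exact 95% confidence interval.
#'
#' @param table 2x2 matrix of non-negative integer counts; rows are the
#'   exposure split, columns the outcome split. Both margins must be
#'   positive.
#' @param conf_level Confidence level for the exact CI.
#' @return Object of class `contingency_result`: list with `table`,
#'   `odds_ratio_sample`, `odds_ratio_cmle`, `ci_low`, `ci_high`,
#'   `p_two_sided`.
#' @export
fisher_enrichment <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a margin is zero (counts: ",
         paste(table, collapse = ", "), ")", call. = FALSE)
  }
  ft <- stats::fisher.test(table, conf.level = conf_level)
  t2 <- if (any(table == 0)) table + 0.5 else table
  or_sample <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  structure(
    list(table = table,
         odds_ratio_sample = or_sample,
         odds_ratio_cmle = unname(ft$estimate),
         ci_low = ft$conf.int[1],
         ci_high = ft$conf.int[2],
         p_two_sided = ft$p.value),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result>\n")
  print(x$table)
  cat(sprintf("OR (sample) %.3g | OR (CMLE) %.3g [%.3g, %.3g] | p = %.3g\n",
              x$odds_ratio_sample, x$odds_ratio_cmle, x$ci_low, x$ci_high,
              x$p_two_sided))
  invisible(x)
}

#' Two-tailed Wilcoxon rank-sum comparison
#'
#' Exact two-sided p-value by enumeration when the pooled sample is small
#' (<= 20) and tie-free; otherwise the normal approximation with mid-ranks,
#' tie correction and continuity correction.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param exact_max Pooled-size bound below which the exact distribution
#'   is used (when tie-free).
#' @return Object of class `group_comparison`: list with `statistic`
#'   (rank-sum W of the first sample), `p_two_sided`, `n_a`, `n_b`,
#'   `method`.
#' @export
wilcoxon_ranksum <- function(a, b, exact_max = 20) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  structure(
    list(statistic = unname(wt$statistic),
         p_two_sided = wt$p.value,
         n_a = length(a), n_b = length(b),
         method = if (exact) "exact" else "normal_approx"),
    class = "group_comparison"
  )
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return Adjusted p-values, `min(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, p_values * m)
}

#' Severity-by-activity contingency analysis
#'
#' Tests whether nearly complete loss of transporter function is enriched
#' among patients with severe disease. Builds a patient-level 2x2 table —
#' rows: complete-LoF variant carriers versus carriers of
#' moderate-LoF/wild-type-like variants; columns: severe versus non-severe
#' disease — and runs [fisher_enrichment()]. Patients whose severity is
#' `other` (unclassifiable) are excluded and their count reported.
#'
#' @param patients Data frame with columns `activity_group` (levels of
#'   [classify_activity_group()]) and `severity` (levels of
#'   [classify_severity()]); one row per patient.
#' @return A `contingency_result` with extra fields `n_excluded_other`
#'   (severity unclassifiable) and `n_excluded_unscored` (no activity
#'   group).
#' @export
severity_by_activity <- function(patients) {
  sev <- as.character(patients$severity)
  grp <- as.character(patients$activity_group)
  drop_other <- !is.na(sev) & sev == "other"
  drop_unscored <- is.na(grp)
  keep <- !drop_other & !drop_unscored
  d <- data.frame(sev = sev[keep], grp = grp[keep])
  tab <- matrix(c(
    sum(d$grp == "complete_lof" & d$sev == "severe"),
    sum(d$grp == "complete_lof" & d$sev == "non_severe"),
    sum(d$grp != "complete_lof" & d$sev == "severe"),
    sum(d$grp != "complete_lof" & d$sev == "non_severe")
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("complete_lof", "moderate_or_wildtype"),
                  c("severe", "non_severe")))
  res <- tryCatch(fisher_enrichment(tab), error = function(e) {
    stop("degenerate severity table (counts: ",
         paste(tab, collapse = ", "), "; excluded other: ",
         sum(drop_other), ", unscored: ", sum(drop_unscored), ")",
         call. = FALSE)
  })
  res$n_excluded_other <- sum(drop_other)
  res$n_excluded_unscored <- sum(drop_unscored)
  res
}

#' Per-domain enrichment of patient versus population variants
#'
#' For each structural domain, builds the 2x2 table
#' `[[patient in domain, patient elsewhere], [population in domain,
#' population elsewhere]]` and tests it with [fisher_enrichment()].
#' Positions outside every interval of the map are excluded from both
#' margins. Counting is at the unique-variant level (`pos`, `ref_aa`,
#' `alt_aa` triples) or at the record/patient level.
#'
#' @param patient_variants,population_variants Data frames with columns
#'   `pos`, `ref_aa`, `alt_aa`.
#' @param map A `domain_map`.
#' @param level `"unique_variant"` (deduplicate on the protein-level
#'   triple) or `"patient"` (count every row).
#' @return Tibble with one row per domain: counts, both odds ratios, the
#'   exact CI, raw p and Bonferroni-adjusted p across the tested domains
#'   (`m` = number of domains tested, recorded in the `m` column).
#' @export
domain_enrichment <- function(patient_variants, population_variants, map,
                              level = c("unique_variant", "patient")) {
  level <- match.arg(level)
  prep <- function(v) {
    if (level == "unique_variant") {
      v <- v[!duplicated(paste(v$pos, v$ref_aa, v$alt_aa)), , drop = FALSE]
    }
    d <- assign_domain(v$pos, map)
    d[d != "unassigned"]
  }
  pat <- prep(patient_variants)
  pop <- prep(population_variants)
  if (length(pat) == 0L || length(pop) == 0L) {
    stop("no assignable variants in one of the sets", call. = FALSE)
  }
  domains <- unique(map$domain_label)
  rows <- lapply(domains, function(dm) {
    tab <- matrix(c(sum(pat == dm), sum(pat != dm),
                    sum(pop == dm), sum(pop != dm)),
                  nrow = 2, byrow = TRUE)
    res <- tryCatch(fisher_enrichment(tab), error = function(e) NULL)
    if (is.null(res)) {
      warning("domain '", dm, "' skipped: degenerate table")
      return(NULL)
    }
    tibble::tibble(domain = dm,
                   n_patient_in = tab[1, 1], n_patient_out = tab[1, 2],
                   n_population_in = tab[2, 1], n_population_out = tab[2, 2],
                   odds_ratio_sample = res$odds_ratio_sample,
                   odds_ratio_cmle = res$odds_ratio_cmle,
                   ci_low = res$ci_low, ci_high = res$ci_high,
                   p = res$p_two_sided)
  })
  out <- dplyr::bind_rows(rows)
  out$m <- nrow(out)
  out$p_bonferroni <- bonferroni(out$p, m = nrow(out))
  out$level <- level
  out
}

#' Pairwise distance comparisons across activity groups
#'
#' For one spatial metric, compares its distribution between each pair of
#' activity groups with the two-tailed Wilcoxon rank-sum test, adjusting
#' across the three pairwise comparisons with Bonferroni (`m = 3` by
#' default, logged in the output).
#'
#' @param variants Data frame with columns `activity_group` and the
#'   metric named by `metric`.
#' @param metric Column name of the distance to compare (e.g.
#'   `"d_ligand"`).
#' @param m Bonferroni multiplier; defaults to the number of pairs.
#' @return Tibble with one row per group pair: group means, n's, W,
#'   raw and adjusted p.
#' @export
distance_group_comparison <- function(variants, metric = "d_ligand",
                                      m = NULL) {
  grp <- as.character(variants$activity_group)
  x <- variants[[metric]]
  keep <- !is.na(grp) & !is.na(x)
  grp <- grp[keep]; x <- x[keep]
  levs <- intersect(c("complete_lof", "moderate_lof", "wildtype_like"),
                    unique(grp))
  if (length(levs) < 2L) {
    return(tibble::tibble(metric = character(), group_a = character(),
                          group_b = character(), n_a = integer(),
                          n_b = integer(), mean_a = numeric(),
                          mean_b = numeric(), statistic = numeric(),
                          p = numeric(), method = character(),
                          m = integer(), p_bonferroni = numeric()))
  }
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  if (is.null(m)) m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- x[grp == pr[1]]; b <- x[grp == pr[2]]
    w <- wilcoxon_ranksum(a, b)
    tibble::tibble(metric = metric, group_a = pr[1], group_b = pr[2],
                   n_a = w$n_a, n_b = w$n_b,
                   mean_a = mean(a), mean_b = mean(b),
                   statistic = w$statistic, p = w$p_two_sided,
                   method = w$method)
  })
  out <- dplyr::bind_rows(rows)
  out$m <- m
  out$p_bonferroni <- bonferroni(out$p, m = m)
  out
}
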