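# Cohort modelling: protein-level variant parsing, GABA-uptake activity
# stratification, structural domain assignment, and binary disease
# severity derived from harmonized epilepsy-syndrome labels.

.AA3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)

#' Parse an HGVS protein-level substitution
#'
#' Accepts three-letter (`p.Val342Met`) and one-letter (`p.V342M`)
#' substitutions, nonsense changes (`Ter`/`*`) and frameshifts (`fs`
#' suffix, with or without a new-stop extension). Nonsense and frameshift
#' changes are classed `truncating_frameshift`; plain substitutions are
#' `missense`.
#'
#' @param hgvs_p A single HGVS `p.` string (the `p.` prefix is optional).
#' @return A list with `pos` (integer), `ref_aa`, `alt_aa` (one-letter;
#'   `"*"` for a stop, `"fs"` for a frameshift) and `consequence`
#'   (`"missense"` or `"truncating_frameshift"`).
#' @details An unparsable string raises a condition of class
#'   `gat1map_hgvs_parse_error` carrying the raw text, so curation scripts
#'   can collect the offenders rather than crash.
#' @export
parse_protein_variant <- function(hgvs_p) {
  raw <- hgvs_p
  x <- trimws(sub("^p\\.", "", trimws(hgvs_p)))
  fail <- function() {
    stop(rlang::error_cnd(
      class = "gat1map_hgvs_parse_error",
      raw = raw,
      message = paste0("cannot parse protein variant: '", raw, "'")
    ))
  }
  if (length(x) != 1L || is.na(x) || x == "") fail()

  aa1 <- function(tok) {
    if (tok %in% .AA3TO1) return(tok)            # already one-letter
    out <- unname(.AA3TO1[tok])
    if (is.na(out)) fail()
    out
  }

  m <- regmatches(x, regexec(
    "^([A-Z][a-z]{2}|[A-Z\\*])([0-9]+)([A-Z][a-z]{2}|[A-Z\\*])(fs.*)?$", x))[[1]]
  if (length(m) == 0L) {
    # frameshift written without an explicit alt residue, e.g. Gly100fs
    m2 <- regmatches(x, regexec("^([A-Z][a-z]{2}|[A-Z])([0-9]+)fs.*$", x))[[1]]
    if (length(m2) == 0L) fail()
    ref <- aa1(m2[2])
    return(list(pos = as.integer(m2[3]), ref_aa = ref, alt_aa = "fs",
                consequence = "truncating_frameshift"))
  }
  ref <- aa1(m[2])
  alt <- aa1(m[4])
  is_fs <- !is.na(m[5]) && nzchar(m[5])
  if (ref == "*" ) fail()
  if (is_fs) {
    return(list(pos = as.integer(m[3]), ref_aa = ref, alt_aa = "fs",
                consequence = "truncating_frameshift"))
  }
  cons <- if (alt == "*") "truncating_frameshift" else "missense"
  list(pos = as.integer(m[3]), ref_aa = ref, alt_aa = alt,
       consequence = cons)
}

#' Parse a vector of HGVS strings into a tibble
#'
#' Vectorized wrapper around [parse_protein_variant()]; unparsable entries
#' become rows with `NA` fields and `parse_ok = FALSE` instead of
#' aborting, so they can be reported individually.
#'
#' @param hgvs_p Character vector.
#' @return Tibble with `hgvs_p`, `pos`, `ref_aa`, `alt_aa`, `consequence`,
#'   `parse_ok`.
#' @export
parse_protein_variants <- function(hgvs_p) {
  rows <- lapply(hgvs_p, function(h) {
    tryCatch({
      p <- parse_protein_variant(h)
      tibble::tibble(hgvs_p = h, pos = p$pos, ref_aa = p$ref_aa,
                     alt_aa = p$alt_aa, consequence = p$consequence,
                     parse_ok = TRUE)
    }, gat1map_hgvs_parse_error = function(e) {
      tibble::tibble(hgvs_p = h, pos = NA_integer_, ref_aa = NA_character_,
                     alt_aa = NA_character_, consequence = NA_character_,
                     parse_ok = FALSE)
    })
  })
  dplyr::bind_rows(rows)
}

#' Stratify GABA-uptake activity into the three functional groups
#'
#' Mean transporter activity relative to wild type is banded into
#' nearly-complete loss of function (< 10%), moderate/low activity
#' (10--42.8%) and wild-type-like (> 42.8%). The 42.8% loss-of-function
#' threshold comes from the behaviour of benign/synonymous-like control
#' variants in the functional assay the readouts derive from. Band edges:
#' 10 belongs to the moderate band and 42.8 to the moderate band
#' (lower-inclusive, upper-inclusive).
#'
#' @param activity_pct Numeric vector of activities (>= 0, % of wild type).
#' @param lof_threshold Wild-type-like boundary; default 42.8.
#' @param complete_threshold Nearly-complete-LoF boundary; default 10.
#' @return Factor with levels `complete_lof`, `moderate_lof`,
#'   `wildtype_like` (`NA` activities map to `NA`).
#' @export
classify_activity_group <- function(activity_pct, lof_threshold = 42.8,
                                    complete_threshold = 10) {
  if (any(activity_pct < 0, na.rm = TRUE)) {
    stop("activity_pct must be >= 0 (percent of wild-type uptake)",
         call. = FALSE)
  }
  out <- ifelse(is.na(activity_pct), NA_character_,
         ifelse(activity_pct < complete_threshold, "complete_lof",
         ifelse(activity_pct <= lof_threshold, "moderate_lof",
                "wildtype_like")))
  factor(out, levels = c("complete_lof", "moderate_lof", "wildtype_like"))
}

.DOMAIN_LABELS <- c("TM1/6", "scaffold", "EL2", "EL3", "EL4", "linker",
                    "TMD-other", "N-terminal", "C-terminal")

#' Build and validate a residue-to-domain map
#'
#' A domain map is a set of 1-based, inclusive, non-overlapping residue
#' intervals labelled with structural domains (`TM1/6`, `scaffold`,
#' `EL2`--`EL4`, `linker`, `TMD-other`, `N-terminal`, `C-terminal`).
#' Labels may repeat across intervals (e.g. TM1 and TM6 both map to
#' `TM1/6`). Overlapping intervals are a configuration error and are
#' rejected at load time.
#'
#' @param entries Data frame with columns `start_pos`, `end_pos`,
#'   `domain_label`.
#' @return A validated tibble of class `domain_map`.
#' @export
domain_map <- function(entries) {
  entries <- tibble::as_tibble(entries)
  req <- c("start_pos", "end_pos", "domain_label")
  if (!all(req %in% names(entries))) {
    stop("domain map needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  entries$start_pos <- as.integer(entries$start_pos)
  entries$end_pos <- as.integer(entries$end_pos)
  if (any(entries$start_pos < 1) || any(entries$end_pos < entries$start_pos)) {
    stop("domain map intervals must be 1-based with end >= start",
         call. = FALSE)
  }
  entries <- entries[order(entries$start_pos), , drop = FALSE]
  if (nrow(entries) > 1L &&
      any(entries$start_pos[-1L] <= entries$end_pos[-nrow(entries)])) {
    stop("domain map intervals overlap", call. = FALSE)
  }
  unknown <- setdiff(unique(entries$domain_label), .DOMAIN_LABELS)
  if (length(unknown)) {
    warning("non-standard domain labels: ", paste(unknown, collapse = ", "))
  }
  class(entries) <- c("domain_map", class(entries))
  entries
}

#' Read a domain map from a TSV file
#' @param path TSV with columns `start_pos`, `end_pos`, `domain_label`.
#' @return A `domain_map`.
#' @export
read_domain_map <- function(path) {
  domain_map(readr::read_tsv(path, show_col_types = FALSE))
}

#' Approximate default GAT1 domain map
#'
#' A synthetic, approximate residue-to-domain map for human GAT1 (UniProt
#' P30531 numbering, 599 aa) assembled from public topology annotations.
#' It is a documented stand-in, suitable for demonstration, not a curated
#' structural annotation.
#'
#' @return A `domain_map`.
#' @export
default_gat1_domain_map <- function() {
  read_domain_map(system.file("extdata", "gat1_domain_map_synthetic.tsv",
                              package = "gat1map", mustWork = TRUE))
}

#' Assign a position to its structural domain
#'
#' @param pos Integer vector of protein positions (1-based).
#' @param map A `domain_map`.
#' @return Character vector of domain labels; `"unassigned"` for positions
#'   outside every interval.
#' @export
assign_domain <- function(pos, map) {
  stopifnot(inherits(map, "domain_map"))
  vapply(as.integer(pos), function(p) {
    hit <- which(map$start_pos <= p & p <= map$end_pos)
    if (length(hit) == 0L) "unassigned" else map$domain_label[hit[1L]]
  }, character(1))
}

.SEVERE_SYNDROMES <- c("DEE", "EMAS", "LGS", "intractable absence epilepsy")
.NON_SEVERE_SYNDROMES <- c("no seizures", "CAE", "unclassified epilepsy",
                           "generalized epilepsy", "GGE", "TLE", "NAFE")

#' Binarize epilepsy syndrome into disease severity
#'
#' The harmonized syndrome labels are collapsed into a binary severity
#' class: DEE, EMAS, LGS and intractable absence epilepsy indicate severe
#' disease (high seizure burden, typically drug-resistant, usually with
#' significant developmental delay); no seizures, CAE, unclassified
#' epilepsy, generalized epilepsy, GGE, TLE and NAFE indicate non-severe
#' disease. Labels outside both lists — including missing data and
#' "intractable primary generalized epilepsy", for which a binary call is
#' not defensible — map to `other`. The mapping is total and idempotent.
#'
#' @param epilepsy_syndrome Character vector of harmonized syndrome
#'   labels (`NA` allowed).
#' @param severe,non_severe Character vectors overriding the default
#'   harmonization dictionaries.
#' @return Factor with levels `severe`, `non_severe`, `other`.
#' @export
classify_severity <- function(epilepsy_syndrome,
                              severe = .SEVERE_SYNDROMES,
                              non_severe = .NON_SEVERE_SYNDROMES) {
  x <- trimws(as.character(epilepsy_syndrome))
  out <- ifelse(is.na(x), "other",
         ifelse(x %in% c(severe, "severe"), "severe",
         ifelse(x %in% c(non_severe, "non_severe"), "non_severe",
                "other")))
  factor(out, levels = c("severe", "non_severe", "other"))
}

#' Per-domain summary of transporter activity
#'
#' For each structural domain: number of scored variants, mean activity
#' (% of wild type), and the count and fraction of variants at or below
#' the loss-of-function threshold. The threshold boundary follows the
#' activity-band convention (activity <= 42.8 counts as low). Domains are
#' ordered by ascending mean activity, so the most functionally
#' compromised domain comes first.
#'
#' @param variants Data frame with columns `pos` and `activity_pct`
#'   (rows with `NA` activity are ignored).
#' @param map A `domain_map`.
#' @param lof_threshold Low-activity boundary; default 42.8.
#' @return Tibble with `domain`, `n`, `mean_activity`, `n_low`,
#'   `frac_low`.
#' @export
domain_activity_summary <- function(variants, map, lof_threshold = 42.8) {
  v <- variants[!is.na(variants$activity_pct), , drop = FALSE]
  if (nrow(v) == 0L) {
    return(tibble::tibble(domain = character(), n = integer(),
                          mean_activity = numeric(), n_low = integer(),
                          frac_low = numeric()))
  }
  v$domain <- assign_domain(v$pos, map)
  out <- v |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_activity = mean(.data$activity_pct),
      n_low = sum(.data$activity_pct <= lof_threshold),
      frac_low = .data$n_low / .data$n,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_activity)
  out
}

#' Partition variants on helix-breaker wild-type residues
#'
#' Glycine and proline disrupt helical geometry ("helix breakers"), so a
#' substitution at such a residue can act through backbone distortion
#' rather than local side-chain chemistry. The distance-versus-activity
#' comparisons are therefore run both with and without them.
#'
#' @param variants Data frame with a `ref_aa` column.
#' @return List with `kept` (ref not G/P) and `removed` (ref G or P);
#'   together an exact partition of the input rows.
#' @export
gly_pro_filter <- function(variants) {
  is_gp <- variants$ref_aa %in% c("G", "P")
  list(kept = variants[!is_gp, , drop = FALSE],
       removed = variants[is_gp, , drop = FALSE])
}

#' Read a variant table
#'
#' Reads a TSV/CSV with either an `hgvs_p` column (parsed via
#' [parse_protein_variants()]) or explicit `pos`/`ref_aa`/`alt_aa`
#' columns. Recognised optional columns: `id`, `source`, `activity_pct`,
#' `clinvar_class`, `allele_frequency`, `consequence`.
#'
#' @param path File path (delimiter inferred from extension; `.csv` is
#'   comma, anything else tab).
#' @return Tibble with one row per record, parse failures flagged in
#'   `parse_ok`.
#' @export
read_variant_table <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  x <- tibble::as_tibble(reader(path, show_col_types = FALSE))
  if (!"id" %in% names(x)) x$id <- sprintf("v%04d", seq_len(nrow(x)))
  for (col in c("pos", "ref_aa", "alt_aa", "consequence")) {
    if (!col %in% names(x)) {
      x[[col]] <- if (col == "pos") NA_integer_ else NA_character_
    }
  }
  # explicit pos/ref/alt wins; rows without it fall back to the HGVS column
  x$parse_ok <- !is.na(x$pos)
  if ("hgvs_p" %in% names(x)) {
    idx <- which(is.na(x$pos) & !is.na(x$hgvs_p))
    if (length(idx)) {
      parsed <- parse_protein_variants(x$hgvs_p[idx])
      x$pos[idx] <- parsed$pos
      x$ref_aa[idx] <- parsed$ref_aa
      x$alt_aa[idx] <- parsed$alt_aa
      x$consequence[idx] <- parsed$consequence
      x$parse_ok[idx] <- parsed$parse_ok
    }
  }
  x$consequence[x$parse_ok & is.na(x$consequence)] <- "missense"
  x
}

#' Read a patient phenotype table
#'
#' Reads a TSV/CSV with columns `patient_id`, `variant_id`,
#' `epilepsy_syndrome` (and optionally `cognitive_level`), then derives
#' the binary `severity` class via [classify_severity()].
#'
#' @param path File path.
#' @return Tibble with a derived `severity` factor column.
#' @export
read_phenotype_table <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  x <- reader(path, show_col_types = FALSE)
  x$severity <- classify_severity(x$epilepsy_syndrome)
  tibble::as_tibble(x)
}
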