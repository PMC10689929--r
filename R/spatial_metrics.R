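# Per-residue spatial metrics on a transporter structure: minimum all-atom
# ligand distance, distance to the transporter axis, distance to designated
# TM segments, and the 5 A neighbourhood-normalized functional score.

.coord_matrix <- function(at, include_hydrogens = FALSE) {
  if (!include_hydrogens) at <- at[!at$is_hydrogen, , drop = FALSE]
  if (nrow(at) == 0L) return(NULL)
  cbind(at$x, at$y, at$z)
}

# minimum Euclidean distance between two point sets (n x 3, m x 3)
.min_pairwise_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Minimum all-atom distance from a residue to the bound ligand
#'
#' Distance in Angstrom between a residue and the ligand group, taken as
#' the minimum over all (residue atom, ligand atom) pairs. Hydrogens are
#' excluded by default: experimental transporter structures rarely resolve
#' them, and including them would make distances depend on protonation.
#'
#' @param s A `protein_structure`.
#' @param seq_num Author residue number.
#' @param include_hydrogens Include hydrogen atoms in the minimum.
#' @return Distance in Angstrom, or `NA_real_` when the residue is not
#'   resolved in the structure.
#' @export
min_distance_to_ligand <- function(s, seq_num, include_hydrogens = FALSE) {
  res <- residue_lookup(s, seq_num)
  if (is.null(res)) return(NA_real_)
  a <- .coord_matrix(res, include_hydrogens)
  b <- .coord_matrix(s$ligand, include_hydrogens)
  if (is.null(a) || is.null(b)) return(NA_real_)
  .min_pairwise_dist(a, b)
}

#' Fit the transporter axis
#'
#' The membrane-normal "transporter axis" is not part of a PDB deposition,
#' so it is constructed from the structure itself. In
#' `"principal_axis_of_segment_CA"` mode (default) the axis is the first
#' principal direction of the C-alpha coordinates of a designated residue
#' segment (typically the union of the core TM helices), anchored at their
#' centroid. In `"fixed_z"` mode the axis is the structure-frame z axis
#' through the ligand centroid, for depositions already oriented along the
#' membrane normal.
#'
#' The direction sign is normalized (largest-magnitude component positive)
#' so repeated fits are identical; point-to-line distances do not depend on
#' the sign.
#'
#' @param s A `protein_structure`.
#' @param segment Integer vector of residue numbers used for the fit
#'   (ignored in `"fixed_z"` mode).
#' @param mode `"principal_axis_of_segment_CA"` or `"fixed_z"`.
#' @return An object of class `axis_definition`: list with `mode`,
#'   `anchor` (3-vector) and `direction` (unit 3-vector).
#' @export
fit_axis <- function(s, segment = NULL,
                     mode = c("principal_axis_of_segment_CA", "fixed_z")) {
  mode <- match.arg(mode)
  if (mode == "fixed_z") {
    lig <- .coord_matrix(s$ligand, include_hydrogens = TRUE)
    anchor <- colMeans(lig)
    direction <- c(0, 0, 1)
  } else {
    at <- s$atoms
    ca <- at[at$elety == "CA" & at$resno %in% segment, , drop = FALSE]
    if (nrow(ca) < 3L) {
      stop("degenerate axis: need >= 3 C-alpha atoms in the segment, got ",
           nrow(ca), call. = FALSE)
    }
    xyz <- cbind(ca$x, ca$y, ca$z)
    anchor <- colMeans(xyz)
    pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
    direction <- pc$rotation[, 1]
    k <- which.max(abs(direction))
    if (direction[k] < 0) direction <- -direction
    direction <- direction / sqrt(sum(direction^2))
  }
  structure(list(mode = mode, anchor = unname(anchor),
                 direction = unname(direction)),
            class = "axis_definition")
}

#' Distance from a residue to the transporter axis
#'
#' Minimum over the residue's heavy atoms of the point-to-line distance to
#' the axis.
#'
#' @inheritParams min_distance_to_ligand
#' @param axis An `axis_definition` from [fit_axis()].
#' @return Distance in Angstrom, or `NA_real_` when unresolved.
#' @export
distance_to_axis <- function(s, seq_num, axis, include_hydrogens = FALSE) {
  stopifnot(inherits(axis, "axis_definition"))
  res <- residue_lookup(s, seq_num)
  if (is.null(res)) return(NA_real_)
  p <- .coord_matrix(res, include_hydrogens)
  if (is.null(p)) return(NA_real_)
  v <- sweep(p, 2, axis$anchor)
  t <- drop(v %*% axis$direction)
  perp <- v - outer(t, axis$direction)
  min(sqrt(rowSums(perp^2)))
}

#' Distance from a residue to a residue segment
#'
#' Minimum heavy-atom distance between a residue and any residue of a
#' segment (e.g. a TM helix). A residue belonging to the segment has
#' distance 0.
#'
#' @inheritParams min_distance_to_ligand
#' @param segment Non-empty integer vector of residue numbers.
#' @return Distance in Angstrom, or `NA_real_` when unresolved.
#' @export
distance_to_segment <- function(s, seq_num, segment,
                                include_hydrogens = FALSE) {
  if (length(segment) == 0L) stop("empty segment", call. = FALSE)
  res <- residue_lookup(s, seq_num)
  if (is.null(res)) return(NA_real_)
  if (seq_num %in% segment) return(0)
  seg <- s$atoms[s$atoms$resno %in% segment, , drop = FALSE]
  a <- .coord_matrix(res, include_hydrogens)
  b <- .coord_matrix(seg, include_hydrogens)
  if (is.null(a) || is.null(b)) return(NA_real_)
  .min_pairwise_dist(a, b)
}

#' Neighbourhood-normalized functional score
#'
#' Smooths per-residue functional activity over the local 3D
#' neighbourhood: the score of a residue is the arithmetic mean of the
#' activities of all scored residues within `radius` Angstrom (default
#' 5), the residue itself included. Residues are neighbours when any heavy
#' atom of one lies within `radius` of any heavy atom of the other
#' (`atom_mode = "all_heavy"`, matching the all-atom ligand-distance
#' convention), or when their C-alpha atoms are within `radius`
#' (`"ca_only"`).
#'
#' @inheritParams min_distance_to_ligand
#' @param scores Named numeric vector of activities (% of wild type),
#'   names are residue numbers.
#' @param radius Neighbourhood radius in Angstrom; "within" is read
#'   inclusively (<= radius).
#' @param atom_mode `"all_heavy"` or `"ca_only"`.
#' @param include_self Include the query residue's own score.
#' @return Mean activity of scored neighbours, or `NA_real_` when the
#'   residue is unresolved or no neighbour carries a score.
#' @export
neighborhood_score <- function(s, seq_num, scores, radius = 5,
                               atom_mode = c("all_heavy", "ca_only"),
                               include_self = TRUE) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(radius > 0)
  res <- residue_lookup(s, seq_num)
  if (is.null(res)) return(NA_real_)
  at <- s$atoms
  if (atom_mode == "ca_only") {
    at <- at[at$elety == "CA", , drop = FALSE]
    res <- res[res$elety == "CA", , drop = FALSE]
  }
  q <- .coord_matrix(res)
  if (is.null(q)) return(NA_real_)
  others <- split(at[!at$is_hydrogen, , drop = FALSE],
                  at$resno[!at$is_hydrogen])
  near <- vapply(others, function(r) {
    .min_pairwise_dist(q, cbind(r$x, r$y, r$z)) <= radius
  }, logical(1))
  nbr <- as.integer(names(others))[near]
  if (!include_self) nbr <- setdiff(nbr, seq_num)
  sc <- scores[as.character(nbr)]
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0L) return(NA_real_)
  mean(sc)
}

#' Per-residue spatial metrics table
#'
#' Computes, for every requested residue position, the minimum ligand
#' distance, distance to the transporter axis, distances to the TM1 and
#' TM6 segments, and the neighbourhood-normalized functional score.
#' Positions absent from the structure are reported with
#' `resolved = FALSE` and `NA` metrics rather than dropped, so curation
#' stays auditable.
#'
#' @param s A `protein_structure`.
#' @param positions Residue numbers to evaluate; default all resolved.
#' @param tm1,tm6 Integer vectors of residue numbers of the two segments.
#' @param scores Optional named activity vector for the neighbourhood
#'   score (see [neighborhood_score()]).
#' @param axis Optional `axis_definition`; default principal axis through
#'   the C-alpha atoms of `union(tm1, tm6)`.
#' @param radius Neighbourhood radius in Angstrom.
#' @return Tibble with columns `seq_num`, `aa`, `d_ligand`, `d_axis`,
#'   `d_tm1`, `d_tm6`, `neighborhood_score`, `resolved`.
#' @export
residue_metrics <- function(s, positions = resolved_positions(s),
                            tm1, tm6, scores = NULL, axis = NULL,
                            radius = 5) {
  if (is.null(axis)) axis <- fit_axis(s, segment = union(tm1, tm6))
  seqs <- residue_sequence(s)
  rows <- lapply(positions, function(p) {
    resolved <- !is.null(residue_lookup(s, p))
    tibble::tibble(
      seq_num  = as.integer(p),
      aa       = if (resolved) unname(seqs[as.character(p)]) else NA_character_,
      d_ligand = min_distance_to_ligand(s, p),
      d_axis   = distance_to_axis(s, p, axis),
      d_tm1    = distance_to_segment(s, p, tm1),
      d_tm6    = distance_to_segment(s, p, tm6),
      neighborhood_score = if (is.null(scores)) NA_real_ else
        neighborhood_score(s, p, scores, radius = radius),
      resolved = resolved
    )
  })
  dplyr::bind_rows(rows)
}
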