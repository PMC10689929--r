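# Deterministic synthetic fixtures: toy helix-bundle structures in PDB
# format with a central ligand, and variant/functional/phenotype tables
# whose statistical structure mirrors what the analysis assumes — activity
# rising with distance from the ligand, patient variants concentrated in
# core domains, and severity enriched among complete-LoF carriers.

.AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic structure and cohort generator.
#' All randomness flows from `seed`; the random-number stream is
#' partitioned per output table (patient positions, population positions,
#' activities, phenotypes) so changing one count leaves the others
#' untouched.
#'
#' Defaults emulate the study conditions the analysis is designed for: a
#' helix bundle around a central ligand whose residues span roughly
#' 7--20 Angstrom of ligand distance; GABA-uptake activity that rises
#' with ligand distance following a logistic curve (midpoint 13 Angstrom,
#' scale 2 Angstrom, so all three activity bands are populated) plus
#' Gaussian noise (sd 10 percentage points,
#' truncated at 0); patient variants concentrated about 8-fold in the
#' core `TM1/6` domain against a uniform population background; and
#' per-group severity rates 0.55 (complete LoF) versus 0.21 (others),
#' a planted odds ratio of about 4.6.
#'
#' @param n_helices,residues_per_helix Bundle geometry (counts).
#' @param bundle_radius Distance of each helix axis from the ligand, in
#'   Angstrom.
#' @param rise_per_residue,twist_deg Ideal alpha-helix parameters
#'   (1.5 Angstrom rise, 100 degree twist per residue).
#' @param helix_radius Backbone radius around the helix axis, Angstrom.
#' @param ligand_position 3-vector, Angstrom.
#' @param n_patient_variants,n_population_variants Cohort sizes.
#' @param activity_model List with `midpoint` (Angstrom), `slope`
#'   (Angstrom, logistic scale; 0 gives a step function) and `noise_sd`
#'   (percentage points).
#' @param severity_model Named numeric vector of P(severe) per activity
#'   group.
#' @param patient_domain_weights Named sampling weights per domain label
#'   for patient variant positions (unnamed domains get weight 1).
#' @param seed Integer seed; mandatory, no implicit randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_helices = 6, residues_per_helix = 20,
                       bundle_radius = 10, rise_per_residue = 1.5,
                       twist_deg = 100, helix_radius = 2.3,
                       ligand_position = c(0, 0, 0),
                       n_patient_variants = 60,
                       n_population_variants = 60,
                       activity_model = list(midpoint = 13, slope = 2,
                                             noise_sd = 10),
                       severity_model = c(complete_lof = 0.55,
                                          moderate_lof = 0.21,
                                          wildtype_like = 0.21),
                       patient_domain_weights = c("TM1/6" = 8),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_helices >= 1, residues_per_helix >= 1, bundle_radius > 0,
            n_patient_variants >= 1, n_population_variants >= 1,
            all(severity_model >= 0 & severity_model <= 1),
            length(ligand_position) == 3)
  structure(list(
    n_helices = n_helices, residues_per_helix = residues_per_helix,
    bundle_radius = bundle_radius, rise_per_residue = rise_per_residue,
    twist_deg = twist_deg, helix_radius = helix_radius,
    ligand_position = ligand_position,
    n_patient_variants = n_patient_variants,
    n_population_variants = n_population_variants,
    activity_model = activity_model, severity_model = severity_model,
    patient_domain_weights = patient_domain_weights,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Synthetic domain map matching the toy bundle
#'
#' Assigns each helix of the bundle to one structural domain label, in a
#' fixed order (`TM1/6`, `scaffold`, `EL4`, `TMD-other`, `N-terminal`,
#' `C-terminal`, then recycling), as contiguous residue intervals.
#'
#' @param cfg A `sim_config`.
#' @return A `domain_map`.
#' @export
sim_domain_map <- function(cfg) {
  labels <- rep(c("TM1/6", "scaffold", "EL4", "TMD-other",
                  "N-terminal", "C-terminal"),
                length.out = cfg$n_helices)
  r <- cfg$residues_per_helix
  domain_map(tibble::tibble(
    start_pos = (seq_len(cfg$n_helices) - 1L) * r + 1L,
    end_pos = seq_len(cfg$n_helices) * r,
    domain_label = labels
  ))
}

#' Build a toy helix bundle around a central ligand
#'
#' Ideal alpha-helix backbones (N, CA, C, O; 1.5 Angstrom rise and
#' 100 degree twist per residue) stand vertically on a circle of
#' `bundle_radius` around the ligand position, which carries a single
#' HETATM atom with hetero-code `"LIG"`. Residues are numbered
#' consecutively across helices on chain A, and amino acids cycle through
#' the 20 standard letters so glycines and prolines occur. Fully
#' deterministic for a given configuration.
#'
#' @param cfg A `sim_config`.
#' @param path Optional file path; when given, the structure is also
#'   written as a PDB file there.
#' @return A `protein_structure` (invisibly also written to `path`).
#' @export
make_helix_bundle <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  H <- cfg$n_helices; R <- cfg$residues_per_helix
  lig <- cfg$ligand_position
  aas <- rep(names(.AA1TO3), length.out = H * R)
  # backbone atom placement: angular/axial/radial offsets from the CA spiral
  offs <- list(
    N  = c(dtheta = -28, dz = -0.50, r = cfg$helix_radius),
    CA = c(dtheta =   0, dz =  0.00, r = cfg$helix_radius),
    C  = c(dtheta =  28, dz =  0.50, r = cfg$helix_radius),
    O  = c(dtheta =  40, dz =  1.00, r = cfg$helix_radius + 0.6)
  )
  rows <- vector("list", H * R * 4L)
  k <- 0L
  for (h in seq_len(H)) {
    phi <- 2 * pi * (h - 1) / H
    cx <- lig[1] + cfg$bundle_radius * cos(phi)
    cy <- lig[2] + cfg$bundle_radius * sin(phi)
    for (j in seq_len(R)) {
      resno <- (h - 1L) * R + j
      theta0 <- j * cfg$twist_deg * pi / 180
      z0 <- lig[3] + (j - (R + 1) / 2) * cfg$rise_per_residue
      for (nm in names(offs)) {
        o <- offs[[nm]]
        th <- theta0 + o[["dtheta"]] * pi / 180
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          chain = "A", resno = resno,
          resname = .AA1TO3[[aas[resno]]], aa = aas[resno],
          elety = nm, element = substr(nm, 1, 1),
          x = cx + o[["r"]] * cos(th), y = cy + o[["r"]] * sin(th),
          z = z0 + o[["dz"]], is_hydrogen = FALSE
        )
      }
    }
  }
  ligand <- tibble::tibble(
    chain = "Z", resno = 1L, resname = "LIG", aa = "X",
    elety = "C1", element = "C",
    x = lig[1], y = lig[2], z = lig[3], is_hydrogen = FALSE
  )
  ps <- structure(
    list(atoms = dplyr::bind_rows(rows), ligand = ligand,
         ligand_code = "LIG", chain = "A", source_id = "synthetic-bundle"),
    class = "protein_structure"
  )
  if (!is.null(path)) write_structure_pdb(ps, path)
  ps
}

.sim_positions <- function(ps, cfg, n, weights_by_domain, seed) {
  set.seed(seed)
  pos <- resolved_positions(ps)
  dmap <- sim_domain_map(cfg)
  dom <- assign_domain(pos, dmap)
  w <- rep(1, length(pos))
  for (dm in names(weights_by_domain)) w[dom == dm] <- weights_by_domain[[dm]]
  sample(pos, n, replace = TRUE, prob = w / sum(w))
}

.sim_activity <- function(d_ligand, am, seed) {
  set.seed(seed)
  mu <- if (am$slope == 0) {
    100 * as.numeric(d_ligand > am$midpoint)
  } else {
    100 * stats::plogis((d_ligand - am$midpoint) / am$slope)
  }
  pmax(0, mu + stats::rnorm(length(d_ligand), 0, am$noise_sd))
}

#' Simulate a variant/functional/phenotype cohort on a structure
#'
#' Patient variant positions are drawn with per-domain weights and
#' population positions uniformly over the resolved residues; the
#' wild-type residue comes from the structure's sequence and the
#' alternate residue is a uniformly drawn different amino acid. GABA
#' uptake for patient variants follows a truncated-at-zero logistic curve
#' of ligand distance plus Gaussian noise. Each patient variant is
#' carried by one simulated patient whose severe/non-severe status is
#' Bernoulli with the per-activity-group probability of
#' `cfg$severity_model` (severe patients get syndrome `DEE`, non-severe
#' `GGE`, so severity re-derivation is exact).
#'
#' @param ps A `protein_structure` (normally from [make_helix_bundle()]).
#' @param cfg A `sim_config`.
#' @return List of tibbles: `variants` (patient + population rows:
#'   `id`, `pos`, `ref_aa`, `alt_aa`, `consequence`, `source`,
#'   `activity_pct`, `d_ligand`), `phenotypes` (`patient_id`,
#'   `variant_id`, `epilepsy_syndrome`), plus the `domain_map` used.
#' @export
simulate_cohort <- function(ps, cfg) {
  stopifnot(inherits(ps, "protein_structure"), inherits(cfg, "sim_config"))
  seqs <- residue_sequence(ps)
  dlig_all <- vapply(resolved_positions(ps),
                     function(p) min_distance_to_ligand(ps, p), numeric(1))
  names(dlig_all) <- resolved_positions(ps)

  pat_pos <- .sim_positions(ps, cfg, cfg$n_patient_variants,
                            cfg$patient_domain_weights, cfg$seed + 1L)
  pop_pos <- .sim_positions(ps, cfg, cfg$n_population_variants,
                            c(), cfg$seed + 2L)

  mk <- function(pos, source, prefix, seed) {
    set.seed(seed)
    ref <- unname(seqs[as.character(pos)])
    alt <- vapply(ref, function(r) sample(setdiff(names(.AA1TO3), r), 1),
                  character(1))
    tibble::tibble(
      id = sprintf("%s%04d", prefix, seq_along(pos)),
      pos = as.integer(pos), ref_aa = ref, alt_aa = unname(alt),
      consequence = "missense", source = source,
      d_ligand = unname(dlig_all[as.character(pos)])
    )
  }
  patients <- mk(pat_pos, "patient", "pv", cfg$seed + 11L)
  population <- mk(pop_pos, "population", "gv", cfg$seed + 12L)

  patients$activity_pct <- .sim_activity(patients$d_ligand,
                                         cfg$activity_model, cfg$seed + 3L)
  population$activity_pct <- NA_real_

  set.seed(cfg$seed + 4L)
  grp <- as.character(classify_activity_group(patients$activity_pct))
  p_sev <- unname(cfg$severity_model[grp])
  severe <- stats::rbinom(nrow(patients), 1, p_sev) == 1
  phenotypes <- tibble::tibble(
    patient_id = sprintf("pt%04d", seq_len(nrow(patients))),
    variant_id = patients$id,
    epilepsy_syndrome = ifelse(severe, "DEE", "GGE")
  )

  list(variants = dplyr::bind_rows(patients, population),
       phenotypes = phenotypes,
       domain_map = sim_domain_map(cfg))
}

#' Write a simulated dataset to disk
#'
#' Emits `structure.pdb`, `variants.tsv`, `phenotypes.tsv`,
#' `domain_map.tsv` and the resolved configuration (`sim_config.yaml`,
#' seed included) into a directory. Identical configurations produce
#' byte-identical files.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated_cohort <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ps <- make_helix_bundle(cfg, path = file.path(dir, "structure.pdb"))
  sim <- simulate_cohort(ps, cfg)
  v <- sim$variants
  v$activity_pct <- round(v$activity_pct, 6)
  v$d_ligand <- round(v$d_ligand, 6)
  readr::write_tsv(v, file.path(dir, "variants.tsv"))
  readr::write_tsv(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  readr::write_tsv(sim$domain_map, file.path(dir, "domain_map.tsv"))
  cfg_plain <- unclass(cfg)
  cfg_plain$severity_model <- as.list(cfg$severity_model)
  cfg_plain$patient_domain_weights <- as.list(cfg$patient_domain_weights)
  yaml::write_yaml(cfg_plain, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
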