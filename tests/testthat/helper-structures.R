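# In-code construction of tiny protein_structure fixtures, so no binary
# or downloaded files are needed anywhere in the suite.

toy_atoms <- function(resno, x, y, z, elety = "CA", aa = "A",
                      element = "C", is_hydrogen = FALSE, chain = "A") {
  tibble::tibble(
    chain = chain, resno = as.integer(resno),
    resname = "ALA", aa = aa, elety = elety, element = element,
    x = x, y = y, z = z, is_hydrogen = is_hydrogen
  )
}

toy_structure <- function(atoms, ligand = NULL, source_id = "toy") {
  if (is.null(ligand)) {
    ligand <- tibble::tibble(
      chain = "Z", resno = 1L, resname = "LIG", aa = "X", elety = "C1",
      element = "C", x = 0, y = 0, z = 0, is_hydrogen = FALSE
    )
  }
  structure(
    list(atoms = atoms, ligand = ligand, ligand_code = "LIG",
         chain = atoms$chain[1], source_id = source_id),
    class = "protein_structure"
  )
}

# random small structure: n_res residues, 1-4 heavy atoms each, plus a
# small multi-atom ligand; coordinates ~ Uniform(-10, 10)
random_toy_structure <- function(n_res = 5, n_lig_atoms = 2) {
  rows <- lapply(seq_len(n_res), function(i) {
    k <- sample(1:4, 1)
    toy_atoms(rep(i, k), x = runif(k, -10, 10), y = runif(k, -10, 10),
              z = runif(k, -10, 10),
              elety = c("CA", "CB", "CG", "CD")[seq_len(k)])
  })
  lig <- tibble::tibble(
    chain = "Z", resno = 1L, resname = "LIG", aa = "X",
    elety = paste0("C", seq_len(n_lig_atoms)), element = "C",
    x = runif(n_lig_atoms, -3, 3), y = runif(n_lig_atoms, -3, 3),
    z = runif(n_lig_atoms, -3, 3), is_hydrogen = FALSE
  )
  toy_structure(dplyr::bind_rows(rows), lig)
}

# random rigid motion: rotation (QR of a random matrix, det +1) and
# translation; applied to every atom including the ligand
apply_rigid_motion <- function(s, rot, trans) {
  move <- function(df) {
    xyz <- cbind(df$x, df$y, df$z) %*% t(rot)
    df$x <- xyz[, 1] + trans[1]
    df$y <- xyz[, 2] + trans[2]
    df$z <- xyz[, 3] + trans[3]
    df
  }
  s$atoms <- move(s$atoms)
  s$ligand <- move(s$ligand)
  s
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  rot <- qr.Q(qr_d)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  rot
}

# the three-residue collinear fixture: single-atom residues at x = 0, 3, 6
collinear_fixture <- function() {
  toy_structure(toy_atoms(1:3, x = c(0, 3, 6), y = 0, z = 0))
}
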