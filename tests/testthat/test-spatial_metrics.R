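# Spatial operators against brute-force oracles, rigid-motion invariance,
# and the hand-enumerated neighbourhood fixture.

test_that("ligand distance matches the exhaustive pairwise oracle", {
  # coincident points
  s0 <- toy_structure(toy_atoms(1, x = 0, y = 0, z = 0))
  expect_equal(min_distance_to_ligand(s0, 1), 0)

  set.seed(101)
  for (rep in 1:20) {
    s <- random_toy_structure(n_res = sample(2:6, 1),
                              n_lig_atoms = sample(1:3, 1))
    for (p in resolved_positions(s)) {
      got <- min_distance_to_ligand(s, p)
      want <- oracle_min_pairwise(heavy_coords(residue_lookup(s, p)),
                                  heavy_coords(s$ligand))
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("distances are invariant under rigid rotation and translation", {
  set.seed(202)
  s <- random_toy_structure(n_res = 6, n_lig_atoms = 2)
  seg <- c(1, 2, 3)
  axis <- fit_axis(s, segment = resolved_positions(s))
  moved <- apply_rigid_motion(s, random_rotation(), rnorm(3, sd = 20))
  axis_m <- fit_axis(moved, segment = resolved_positions(moved))
  for (p in resolved_positions(s)) {
    expect_equal(min_distance_to_ligand(moved, p),
                 min_distance_to_ligand(s, p), tolerance = 1e-6)
    expect_equal(distance_to_segment(moved, p, seg),
                 distance_to_segment(s, p, seg), tolerance = 1e-6)
    expect_equal(distance_to_axis(moved, p, axis_m),
                 distance_to_axis(s, p, axis), tolerance = 1e-6)
  }
  # translation alone, checked on the ligand distance example
  shifted <- apply_rigid_motion(s, diag(3), c(5, -3, 11))
  expect_equal(min_distance_to_ligand(shifted, 1),
               min_distance_to_ligand(s, 1), tolerance = 1e-6)
})

test_that("axis fitting recovers collinear and random-cloud directions", {
  # C-alphas along an exact line: direction parallel to it
  d <- c(1, 2, 2) / 3
  line_pts <- outer(0:9, d)
  s <- toy_structure(toy_atoms(1:10, x = line_pts[, 1], y = line_pts[, 2],
                               z = line_pts[, 3]))
  ax <- fit_axis(s, segment = 1:10)
  expect_gt(abs(sum(ax$direction * d)), 0.999)
  expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-12)

  # 20 random points: matches the covariance eigenvector oracle
  set.seed(303)
  xyz <- matrix(rnorm(60, sd = c(4, 1, 1)), ncol = 3, byrow = TRUE)
  s2 <- toy_structure(toy_atoms(1:20, x = xyz[, 1], y = xyz[, 2],
                                z = xyz[, 3]))
  ax2 <- fit_axis(s2, segment = 1:20)
  want <- oracle_principal_direction(xyz)
  expect_gt(abs(sum(ax2$direction * want)), 1 - 1e-9)

  # fixed_z ignores the coordinates entirely
  ax3 <- fit_axis(s2, mode = "fixed_z")
  expect_equal(ax3$direction, c(0, 0, 1))

  # degenerate: fewer than 3 C-alphas
  expect_error(fit_axis(s, segment = 1:2), "degenerate axis")
})

test_that("axis distance equals the per-atom point-line oracle", {
  lig <- tibble::tibble(chain = "Z", resno = 1L, resname = "LIG", aa = "X",
                        elety = "C1", element = "C", x = 0, y = 0, z = 0,
                        is_hydrogen = FALSE)
  s <- toy_structure(toy_atoms(1:2, x = c(0, 7), y = c(0, 0), z = c(3, 2)),
                     ligand = lig)
  ax <- fit_axis(s, mode = "fixed_z")
  expect_equal(distance_to_axis(s, 1, ax), 0)      # on the axis
  expect_equal(distance_to_axis(s, 2, ax), 7)      # cylinder radius

  set.seed(404)
  s2 <- random_toy_structure(n_res = 5)
  ax2 <- fit_axis(s2, segment = resolved_positions(s2))
  for (p in resolved_positions(s2)) {
    pts <- heavy_coords(residue_lookup(s2, p))
    want <- min(vapply(seq_len(nrow(pts)), function(i) {
      v <- pts[i, ] - ax2$anchor
      sqrt(sum(v^2) - sum(v * ax2$direction)^2)
    }, numeric(1)))
    expect_equal(distance_to_axis(s2, p, ax2), want, tolerance = 1e-6)
  }
})

test_that("segment distance is a pairwise minimum with self-distance zero", {
  set.seed(505)
  s <- random_toy_structure(n_res = 6)
  seg <- c(2, 4)
  expect_equal(distance_to_segment(s, 2, seg), 0)
  for (p in setdiff(resolved_positions(s), seg)) {
    seg_atoms <- s$atoms[s$atoms$resno %in% seg, ]
    want <- oracle_min_pairwise(heavy_coords(residue_lookup(s, p)),
                                heavy_coords(seg_atoms))
    expect_equal(distance_to_segment(s, p, seg), want, tolerance = 1e-6)
    # enlarging the segment never increases the distance
    expect_lte(distance_to_segment(s, p, c(seg, 5)),
               distance_to_segment(s, p, seg) + 1e-12)
  }
  expect_error(distance_to_segment(s, 1, integer(0)), "empty segment")
})

test_that("neighbourhood score reproduces the hand-enumerated fixture", {
  s <- collinear_fixture()          # residues at x = 0, 3, 6
  sc <- c(`1` = 0, `2` = 50, `3` = 100)
  # ends see themselves + the middle (3 A); middle sees all three
  expect_equal(neighborhood_score(s, 1, sc), 25)
  expect_equal(neighborhood_score(s, 2, sc), 50)
  expect_equal(neighborhood_score(s, 3, sc), 75)

  # isolated scored residue averages to its own score
  iso <- toy_structure(toy_atoms(1:2, x = c(0, 100), y = 0, z = 0))
  expect_equal(neighborhood_score(iso, 2, c(`2` = 33)), 33)
  # no scored neighbour: undefined
  expect_true(is.na(neighborhood_score(iso, 1, c(`2` = 33))))
  # excluding the query residue drops its own score from the average
  expect_equal(neighborhood_score(s, 1, sc, include_self = FALSE), 50)
})

test_that("neighbourhood score is affine-equivariant and constant-stable", {
  set.seed(606)
  s <- random_toy_structure(n_res = 8)
  pos <- resolved_positions(s)
  sc <- stats::setNames(runif(length(pos), 0, 100), pos)
  base <- vapply(pos, function(p) neighborhood_score(s, p, sc), numeric(1))
  trans <- vapply(pos, function(p) neighborhood_score(s, p, 3 * sc + 7),
                  numeric(1))
  expect_equal(trans, 3 * base + 7, tolerance = 1e-9)

  const <- stats::setNames(rep(42, length(pos)), pos)
  expect_true(all(vapply(pos, function(p)
    neighborhood_score(s, p, const), numeric(1)) == 42))
})

test_that("the score lies within the range of contributing scores", {
  set.seed(707)
  for (rep in 1:5) {
    s <- random_toy_structure(n_res = 6)
    pos <- resolved_positions(s)
    sc <- stats::setNames(runif(length(pos), 0, 100), pos)
    for (p in pos) {
      v <- neighborhood_score(s, p, sc)
      expect_gte(v, min(sc))
      expect_lte(v, max(sc))
    }
  }
})
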