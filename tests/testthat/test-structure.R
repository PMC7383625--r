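test_that("a minimal hand-written PDB round-trips exact coordinates", {
  txt <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500  -1.250   0.125  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       0.001   0.002   0.003  1.00  0.00           C",
    "END"
  )
  m <- parse_structure(write_pdb_tempfile(txt))
  expect_identical(nrow(m$atoms), 3L)
  expect_equal(m$atoms$x, c(1, 2.5, 0.001))
  expect_equal(m$atoms$y, c(2, -1.25, 0.002))
  expect_equal(m$atoms$z, c(3, 0.125, 0.003))
  expect_identical(m$atoms$element, c("N", "C", "C"))
})

test_that("the highest-occupancy altloc is kept and waters are excluded", {
  txt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   1.000   1.000  0.30  0.00           C",
    "ATOM      4  CB BALA A   1       2.000   1.000   1.000  0.70  0.00           C",
    "ATOM      5  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"
  )
  m <- parse_structure(write_pdb_tempfile(txt))
  expect_identical(nrow(m$atoms), 2L)
  ca <- m$atoms[trimws(m$atoms$name) == "CA", ]
  expect_equal(ca$x, 0) # the 0.60-occupancy A conformer
  cb <- m$atoms[trimws(m$atoms$name) == "CB", ]
  expect_equal(cb$x, 2) # the 0.70-occupancy B conformer
})

test_that("empty or atom-free files are rejected", {
  tf <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", tf)
  expect_error(parse_structure(tf))
})

test_that("an isolated sphere's SASA matches the closed form within 1%", {
  for (el in c("C", "O", "S")) {
    m <- parse_structure(write_pdb_tempfile(gen_toy_structure("single-atom", element = el)))
    sa <- shrake_rupley_sasa(m, probe_radius = 1.4, n_points = 960)
    r <- c(C = 1.70, O = 1.52, S = 1.80)[[el]]
    exact <- 4 * pi * (r + 1.4)^2
    expect_lt(abs(sa$total - exact) / exact, 0.01)
  }
})

test_that("non-overlapping spheres each retain their isolated SASA", {
  d_big <- 1.7 + 1.7 + 2 * 1.4 + 0.5
  m <- parse_structure(write_pdb_tempfile(gen_toy_structure("two-sphere", separation = d_big)))
  sa <- shrake_rupley_sasa(m)
  iso <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(sa$area[1], iso, tolerance = 0.01)
  expect_equal(sa$area[2], iso, tolerance = 0.01)
})

test_that("overlapping spheres match an independent grid-integration oracle within 2%", {
  for (d in c(2.0, 3.5, 5.0)) {
    m <- parse_structure(write_pdb_tempfile(gen_toy_structure("two-sphere", separation = d)))
    sa <- shrake_rupley_sasa(m)
    oracle <- grid_sasa_sphere1(1.7, 1.7, d, 1.4)
    expect_lt(abs(sa$area[1] - oracle) / oracle, 0.02)
    # symmetric geometry: both atoms equal
    expect_equal(sa$area[1], sa$area[2], tolerance = 0.01)
    # and the closed-form spherical-cap area agrees
    closed <- two_sphere_sasa_closed_form(1.7, 1.7, d, 1.4)
    expect_lt(abs(sa$area[1] - closed) / closed, 0.02)
  }
})

test_that("unknown elements error unless a default radius is configured", {
  txt <- "ATOM      1 FE1  UNK A   1       0.000   0.000   0.000  1.00  0.00          FE"
  m <- parse_structure(write_pdb_tempfile(txt))
  expect_error(shrake_rupley_sasa(m), "FE")
  sa <- shrake_rupley_sasa(m, default_radius = 1.6)
  expect_equal(sa$total, 4 * pi * 3^2, tolerance = 0.01)
})

test_that("hydrophobic classification is the carbon/sulfur rule", {
  txt <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.200   1.300   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       3.400   1.400   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.100  -1.300   0.000  1.00  0.00           C",
    "ATOM      6  SD  MET A   2       6.000   0.000   0.000  1.00  0.00           S"
  )
  m <- parse_structure(write_pdb_tempfile(txt))
  hyd <- classify_hydrophobic_atoms(m)
  expect_identical(trimws(m$atoms$name[hyd]), c("CA", "C", "CB", "SD"))
  expect_identical(trimws(m$atoms$name[!hyd]), c("N", "O"))

  no_c <- "ATOM      1  O   UNK A   1       0.000   0.000   0.000  1.00  0.00           O"
  expect_identical(sum(classify_hydrophobic_atoms(parse_structure(write_pdb_tempfile(no_c)))), 0L)
})

test_that("hydrophobic + polar SASA partition the total exactly", {
  m <- parse_structure(write_pdb_tempfile(gen_toy_structure("helix", n_res = 20, seed = 5)))
  p <- define_pocket(m, triad = 10, cutoff = 8)
  surf <- hydrophobic_pocket_area(m, p, n_points = 480)
  expect_equal(surf$hydrophobic_sasa + surf$polar_sasa, surf$total_sasa, tolerance = 1e-9)
  expect_lte(surf$pocket_area, surf$hydrophobic_sasa)
  expect_gte(surf$pocket_area, 0)
})

test_that("a larger probe never raises an atom's SASA-to-isolated-sphere ratio above 1", {
  m <- parse_structure(write_pdb_tempfile(gen_toy_structure("helix", n_res = 12, seed = 2)))
  for (w in c(1.0, 1.4, 2.0)) {
    sa <- shrake_rupley_sasa(m, probe_radius = w, n_points = 480)
    iso <- 4 * pi * (sa$radii + w)^2
    expect_true(all(sa$area / iso <= 1 + 1e-12))
  }
})

test_that("doubling the point count changes total SASA by < 0.5%", {
  m <- parse_structure(write_pdb_tempfile(gen_toy_structure("helix", n_res = 20, seed = 3)))
  s1 <- shrake_rupley_sasa(m, n_points = 960)
  s2 <- shrake_rupley_sasa(m, n_points = 1920)
  expect_lt(abs(s1$total - s2$total) / s2$total, 0.005)
})

test_that("pocket definition follows the serine O-gamma distance rule", {
  # serine with OG at origin, one residue 5 A away, one 15 A away
  txt <- c(
    "ATOM      1  CB  SER A  10       0.000   0.000  -1.500  1.00  0.00           C",
    "ATOM      2  OG  SER A  10       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      3  CA  LEU A  11       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  LEU A  12      15.000   0.000   0.000  1.00  0.00           C"
  )
  m <- parse_structure(write_pdb_tempfile(txt))
  p <- define_pocket(m, triad = 10, cutoff = 10)
  expect_identical(p$residues, c(10L, 11L))

  p0 <- define_pocket(m, triad = 10, cutoff = 0)
  expect_identical(p0$residues, 10L)

  expect_error(define_pocket(m, triad = c(146, 240, 270)), "146")
})

test_that("a whole-structure pocket recovers the total hydrophobic SASA", {
  m <- parse_structure(write_pdb_tempfile(gen_toy_structure("helix", n_res = 15, seed = 4)))
  sa <- shrake_rupley_sasa(m, n_points = 480)
  p_all <- define_pocket(m, triad = 8, cutoff = 1e6)
  surf <- hydrophobic_pocket_area(m, p_all, sasa = sa)
  expect_equal(surf$pocket_area, surf$hydrophobic_sasa, tolerance = 1e-12)
})

test_that("pocket area is monotone non-decreasing in the cutoff radius", {
  m <- parse_structure(write_pdb_tempfile(gen_toy_structure("helix", n_res = 30, seed = 6)))
  sa <- shrake_rupley_sasa(m, n_points = 480)
  areas <- vapply(c(4, 6, 8, 12, 20, 40), function(cutoff) {
    hydrophobic_pocket_area(m, define_pocket(m, triad = 15, cutoff = cutoff), sasa = sa)$pocket_area
  }, numeric(1))
  expect_true(all(diff(areas) >= -1e-12))
})

test_that("correlation handles exact lines, matches a raw-sums oracle, and rejects degenerate input", {
  x <- c(1, 2, 3, 4.5, 7)
  expect_equal(correlate_scores_areas(x, 3 + 2 * x)$r, 1, tolerance = 1e-12)
  expect_equal(correlate_scores_areas(x, 10 - 0.5 * x)$r, -1, tolerance = 1e-12)

  set.seed(3)
  a <- stats::rnorm(100)
  b <- 0.6 * a + stats::rnorm(100)
  r_pkg <- correlate_scores_areas(a, b)$r
  expect_equal(r_pkg, pearson_raw_sums(a, b), tolerance = 1e-12)
  expect_equal(r_pkg, stats::cor(a, b), tolerance = 1e-12)

  expect_error(correlate_scores_areas(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate_scores_areas(c(1, 2), c(1, 2)), "at least 3")
})
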