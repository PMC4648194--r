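# PDB parsing, distances/dihedrals, pocket geometry and superposition.

pocket_fixture <- function(distances = list(proximal = 2.10, distal = 6.71),
                           dihedrals = NULL) {
  parse_structure(generate_heme_pocket_pdb(distances, dihedrals))
}

test_that("synthetic pockets parse losslessly and round-trip coordinates", {
  pdb <- generate_heme_pocket_pdb(list(proximal = 2.10, distal = 6.71,
                                       B10 = 4.5, CD1 = 5.25))
  m <- parse_structure(pdb)
  expect_equal(nrow(m$fe), 1)
  rewritten <- write_pdb(m$atoms)
  m2 <- parse_structure(rewritten)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_equal(m2$atoms$name, m$atoms$name)
})

test_that("parser agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(generate_heme_pocket_pdb(list(proximal = 2.1)), path)
  ours <- parse_structure(path)
  theirs <- suppressWarnings(bio3d::read.pdb(path))
  expect_equal(ours$atoms$x, theirs$atom$x, tolerance = 1e-9)
  expect_equal(ours$atoms$y, theirs$atom$y, tolerance = 1e-9)
  expect_equal(ours$atoms$resno, theirs$atom$resno)
})

test_that("structures without heme or Fe and malformed records are rejected", {
  no_heme <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  expect_error(parse_structure(no_heme), "no heme")
  short <- "ATOM      1  CA"
  expect_error(parse_structure(short), "line 1")
  bad_num <- "HETATM    1 FE   HEM A 154       x.000   0.000   0.000  1.00  0.00          FE"
  expect_error(parse_structure(bad_num), "malformed x field at line 1")
})

test_that("distances follow the Euclidean definition two ways", {
  expect_equal(atom_distance(c(0, 0, 0), c(0, 0, 2.10)), 2.10)
  expect_equal(atom_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(111)
  for (k in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    # expanded dot-product form as the second, independent formula
    alt <- sqrt(sum(a * a) + sum(b * b) - 2 * sum(a * b))
    expect_equal(atom_distance(a, b), alt, tolerance = 1e-12)
  }
})

test_that("dihedrals use the IUPAC sign convention", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)), -90)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 180)
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               "coincide")
  expect_warning(v <- dihedral(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)),
                 "degenerate")
  expect_true(is.na(v))
})

test_that("planted distances and dihedrals are reproduced within tolerance", {
  m <- pocket_fixture(
    distances = list(proximal = 2.10, distal = 6.71, B10 = 4.50, CD1 = 5.25),
    dihedrals = list(proximal = -90.0, distal = 63.4, B10 = 170.0, CD1 = -12.5)
  )
  p <- pocket_geometry(m, synthetic_pocket_roles())
  g <- p$geometry
  expect_equal(g$distance[g$role == "proximal"], 2.10, tolerance = 1e-3)
  expect_equal(g$distance[g$role == "distal"], 6.71, tolerance = 1e-3)
  expect_equal(g$distance[g$role == "B10"], 4.50, tolerance = 1e-3)
  expect_equal(g$distance[g$role == "CD1"], 5.25, tolerance = 1e-3)
  expect_equal(g$chi1[g$role == "proximal"], -90.0, tolerance = 0.1)
  expect_equal(g$chi1[g$role == "distal"], 63.4, tolerance = 0.1)
  expect_equal(g$chi1[g$role == "B10"], 170.0, tolerance = 0.1)
  expect_equal(g$chi1[g$role == "CD1"], -12.5, tolerance = 0.1)
})

test_that("unrealizable pocket requests are rejected", {
  expect_error(generate_heme_pocket_pdb(list(proximal = -2)), "positive")
  expect_error(generate_heme_pocket_pdb(list(E7 = 2)), "unknown role")
  expect_error(generate_heme_pocket_pdb(list()), "at least one role")
})

test_that("coordination calls follow the cutoff rule", {
  penta <- pocket_geometry(pocket_fixture(list(proximal = 2.10, distal = 6.71)),
                           synthetic_pocket_roles()[c("proximal", "distal")])
  expect_equal(penta$coordination, "penta")
  hexa <- pocket_geometry(pocket_fixture(list(proximal = 2.0, distal = 2.4)),
                          synthetic_pocket_roles()[c("proximal", "distal")])
  expect_equal(hexa$coordination, "hexa")
  indet <- pocket_geometry(pocket_fixture(list(proximal = 7.5, distal = 8.2)),
                           synthetic_pocket_roles()[c("proximal", "distal")])
  expect_equal(indet$coordination, "indeterminate")
})

test_that("geometry is invariant under rigid motions", {
  m <- pocket_fixture(
    distances = list(proximal = 2.10, distal = 6.71, B10 = 4.50),
    dihedrals = list(proximal = -90.0)
  )
  p0 <- pocket_geometry(m, synthetic_pocket_roles()[c("proximal", "distal", "B10")])
  set.seed(112)
  for (k in 1:5) {
    m2 <- transform_structure(m, random_rotation(), rnorm(3, sd = 20))
    p2 <- pocket_geometry(m2, synthetic_pocket_roles()[c("proximal", "distal", "B10")])
    expect_equal(p2$geometry$distance, p0$geometry$distance, tolerance = 1e-9)
    expect_equal(p2$geometry$chi1, p0$geometry$chi1, tolerance = 1e-9)
    expect_equal(p2$coordination, p0$coordination)
  }
})

test_that("a missing probe atom falls back to the nearest side-chain atom", {
  m <- pocket_fixture(list(proximal = 2.10))
  # request a probe atom the residue does not have
  expect_warning(
    p <- pocket_geometry(m, list(proximal = c(93, "OH"))),
    "using nearest side-chain atom"
  )
  expect_true(p$geometry$probe_atom %in% c("CB", "CG", "ND1", "CE1", "NE2", "CD2"))
})

test_that("Kabsch superposition is exact, proper and optimal", {
  m <- pocket_fixture(list(proximal = 2.10, distal = 6.71))
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  self <- kabsch_superpose(xyz, xyz)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(det(self$rotation), 1, tolerance = 1e-9)

  set.seed(113)
  R <- random_rotation(); t0 <- rnorm(3, sd = 10)
  moved <- sweep(xyz %*% t(R), 2, t0, `+`)
  fit <- kabsch_superpose(xyz, moved)
  expect_lt(fit$rmsd, 1e-6)
  # closed form beats random rigid motions
  centered_a <- sweep(xyz, 2, colMeans(xyz))
  centered_b <- sweep(moved, 2, colMeans(moved))
  for (k in 1:200) {
    Rr <- random_rotation()
    rmsd_r <- sqrt(mean(rowSums((centered_a - centered_b %*% t(Rr))^2)))
    expect_gte(rmsd_r, fit$rmsd - 1e-9)
  }
  expect_error(kabsch_superpose(xyz[1:2, ], xyz[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("noisy-copy RMSD matches its Monte-Carlo expectation", {
  set.seed(114)
  n <- 50
  base <- matrix(rnorm(n * 3, sd = 8), n, 3)
  sigma <- 0.1
  rmsds <- vapply(1:40, function(k) {
    noisy <- base + matrix(rnorm(n * 3, sd = sigma), n, 3)
    kabsch_superpose(base, noisy)$rmsd
  }, numeric(1))
  expected <- sigma * sqrt(3) * sqrt(1 - 6 / (3 * n))
  se <- sd(rmsds) / sqrt(length(rmsds))
  expect_lt(abs(mean(rmsds) - expected), 3 * se + 0.005)
})
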