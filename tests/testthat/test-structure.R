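test_that("PDB parsing keeps coordinates and applies the altloc rule", {
  path <- tempfile(fileext = ".pdb")
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1))
  write_toy_pdb(path, 1:3, c("N", "CA", "C"), "GLY", "A", c(1, 1, 1),
                xyz, c("N", "C", "C"))
  s <- read_pdb(path)
  expect_equal(nrow(s), 3)
  expect_equal(as.matrix(s[, c("x", "y", "z")]), xyz,
               ignore_attr = TRUE)
  expect_equal(s$radius, c(1.55, 1.70, 1.70))
  ca <- read_pdb(path, "CA")
  expect_equal(nrow(ca), 1)

  # altloc A/B duplicate: only A kept
  path2 <- tempfile(fileext = ".pdb")
  write_toy_pdb(path2, 1:2, c("CA", "CA"), "ALA", "A", c(1, 1),
                rbind(c(0, 0, 0), c(9, 9, 9)), c("C", "C"),
                altloc = c("A", "B"))
  s2 <- read_pdb(path2)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$x, 0)

  # empty after filter
  path3 <- tempfile(fileext = ".pdb")
  write_toy_pdb(path3, 1, "SG", "CYS", "A", 1, rbind(c(0, 0, 0)), "S")
  expect_error(read_pdb(path3, "CA"), "no atoms")
})

test_that("Kabsch superposition is exact under rigid motion", {
  set.seed(8)
  A <- matrix(rnorm(30), 10, 3)
  self <- kabsch_superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  # random rotation + translation
  ang <- runif(3, -pi, pi)
  Rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0,
                 sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[3]), -sin(ang[3]),
                 0, sin(ang[3]), cos(ang[3])), 3, byrow = TRUE)
  B <- A %*% t(Rz %*% Rx) + matrix(c(5, -2, 7), 10, 3, byrow = TRUE)
  sp <- kabsch_superpose(A, B)
  expect_lt(sp$rmsd, 1e-8)
  # rotation is orthonormal with det +1
  expect_equal(t(sp$rotation) %*% sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # symmetry of the metric
  C <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(A, C)$rmsd, kabsch_superpose(C, A)$rmsd,
               tolerance = 1e-9)
  expect_error(kabsch_superpose(A[1:2, ], C[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches a rotation-search oracle", {
  set.seed(14)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(12), 4, 3)
  got <- kabsch_superpose(A, B)$rmsd
  want <- oracle_min_rmsd(A, B)
  expect_equal(got, want, tolerance = 1e-3)
  expect_lte(got, want + 1e-6)   # Kabsch is the true minimum
})

test_that("residue pair distances are plain Euclidean lookups", {
  s <- structure_from_atoms(rbind(c(0, 0, 0), c(3, 4, 0)), element = "S",
                            resno = c(61, 107), resid = "CYS",
                            elety = "SG")
  expect_equal(residue_pair_distance(s, 61, 107, "SG"), 5)
  expect_equal(residue_pair_distance(s, 61, 61, "SG"), 0)
  expect_error(residue_pair_distance(s, 61, 99, "SG"), "residue 99")
  # planted disulfide geometry: SG atoms 14.3 A apart
  s2 <- structure_from_atoms(rbind(c(0, 0, 0), c(14.3, 0, 0)),
                             element = "S", resno = c(61, 107),
                             resid = "CYS", elety = "SG")
  expect_equal(residue_pair_distance(s2, 61, 107), 14.3)
})

test_that("SASA reproduces the analytic sphere and separated atoms", {
  one <- structure_from_atoms(rbind(c(0, 0, 0)), element = "C")
  a1 <- shrake_rupley_sasa(one, probe = 1.4, n_points = 960)$sasa
  expect_equal(a1, 4 * pi * 3.1^2, tolerance = 0.01)
  two <- structure_from_atoms(rbind(c(0, 0, 0), c(100, 0, 0)),
                              element = "C", resno = c(1, 2))
  a2 <- shrake_rupley_sasa(two, probe = 1.4, n_points = 960)$sasa
  expect_equal(sum(a2), 2 * 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("occlusion removes area and matches a direct point count", {
  # central atom caged by an icosahedral-ish shell of close neighbors
  shell <- gpxlike:::sphere_points(30) * 2.2
  caged <- structure_from_atoms(rbind(c(0, 0, 0), shell), element = "C",
                                resno = c(1, rep(2, 30)))
  sasa <- shrake_rupley_sasa(caged, probe = 1.4, n_points = 480)$sasa
  expect_lt(sasa[1], 1)                        # essentially buried

  # half-occluded pair: direct point-count oracle on the same test points
  pair <- structure_from_atoms(rbind(c(0, 0, 0), c(2.0, 0, 0)),
                               element = "C", resno = c(1, 2))
  got <- shrake_rupley_sasa(pair, probe = 1.4, n_points = 960)$sasa
  pts <- gpxlike:::sphere_points(960)
  rr <- 1.7 + 1.4
  direct <- vapply(1:2, function(i) {
    center <- if (i == 1) c(0, 0, 0) else c(2, 0, 0)
    other <- if (i == 1) c(2, 0, 0) else c(0, 0, 0)
    p <- sweep(pts * rr, 2, center, `+`)
    free <- sqrt(rowSums(sweep(p, 2, other)^2)) > rr
    4 * pi * rr^2 * sum(free) / 960
  }, 0)
  expect_equal(got, direct, tolerance = 1e-12)

  # monotonicity: adding a neighbor never increases area
  solo <- shrake_rupley_sasa(structure_from_atoms(rbind(c(0, 0, 0)),
                                                  element = "C"))$sasa
  expect_lte(got[1], solo + 1e-9)
})

test_that("relative accessibility normalizes by reference maxima", {
  # reference computed from the same free residue: exactly 100%
  res <- structure_from_atoms(rbind(c(0, 0, 0), c(1.5, 0, 0)),
                              element = c("C", "C"), resno = 1,
                              resid = "ALA", elety = c("CA", "CB"))
  res <- shrake_rupley_sasa(res)
  own_ref <- c(ALA = sum(res$sasa))
  expect_equal(relative_accessibility(res, 1, reference_max = own_ref), 100)
  # buried residue: near 0
  shell <- gpxlike:::sphere_points(40) * 2.2
  buried <- structure_from_atoms(rbind(c(0, 0, 0), shell), element = "C",
                                 resno = c(1, rep(2, 40)),
                                 resid = c("ALA", rep("GLY", 40)))
  buried <- shrake_rupley_sasa(buried, n_points = 480)
  expect_lt(relative_accessibility(buried, 1), 2)
  expect_error(relative_accessibility(res, 1,
                                      reference_max = c(GLY = 104)),
               "missing from the reference")
  expect_error(relative_accessibility(res, 9), "not found")
})
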