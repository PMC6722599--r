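# Source spaces, meshes, montages, spherical forward model.

test_that("icosphere vertex counts and radii follow the tessellation formula", {
  expect_equal(nrow(make_sphere_source_space(2, 70)$vertices), 162L)
  s3 <- make_sphere_source_space(3, 70)
  expect_equal(nrow(s3$vertices), 642L)
  expect_lt(max(abs(sqrt(rowSums(s3$vertices^2)) - 70)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(s3$orientations^2)) - 1)), 1e-9)
  expect_error(make_sphere_source_space(0), class = "ezloc_parameter_error")
})

test_that("mesh adjacency is symmetric", {
  s <- make_sphere_source_space(2, 50)
  for (v in c(1L, 50L, 162L))
    for (nb in s$adjacency[[v]])
      expect_true(v %in% s$adjacency[[nb]])
})

test_that("OFF and OBJ surfaces round-trip with radial normals", {
  s <- make_sphere_source_space(2, 65)
  p <- file.path(tempdir(), "sph.off")
  write_surface(s, p)
  r <- load_surface(p)
  expect_equal(r$vertices, s$vertices, tolerance = 1e-6)
  expect_lt(max(abs(rowSums(r$orientations * s$orientations) - 1)), 1e-3)

  # OBJ path
  po <- file.path(tempdir(), "sph.obj")
  writeLines(c(apply(s$vertices, 1, function(v)
    sprintf("v %.9g %.9g %.9g", v[1], v[2], v[3])),
    apply(s$faces, 1, function(f) sprintf("f %d %d %d", f[1], f[2], f[3]))),
    po)
  r2 <- load_surface(po)
  expect_equal(r2$vertices, s$vertices, tolerance = 1e-6)
})

test_that("degenerate faces and unreferenced vertices follow declared policy", {
  p <- file.path(tempdir(), "degen.off")
  # a tetrahedron plus a zero-area face and an unreferenced vertex
  writeLines(c("OFF", "5 5 0",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1", "9 9 9",
               "3 0 2 1", "3 0 1 3", "3 1 2 3", "3 0 3 2",
               "3 0 0 0"), p)
  expect_warning(expect_warning(load_surface(p),
                                class = "ezloc_mesh_warning"),
                 class = "ezloc_mesh_warning")
  src <- suppressWarnings(load_surface(p))
  expect_equal(nrow(src$vertices), 4L)

  # cube mesh: vertex normals point outward
  cube_v <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  hull <- t(matrix(c(1,3,2, 2,3,4, 5,6,7, 6,8,7, 1,2,5, 2,6,5,
                     3,7,4, 4,7,8, 1,5,3, 3,5,7, 2,4,6, 4,8,6), 3))
  pc <- file.path(tempdir(), "cube.off")
  writeLines(c("OFF", "8 12 0",
               apply(cube_v, 1, paste, collapse = " "),
               apply(hull - 1, 1, function(f) paste(c(3, f), collapse = " "))),
             pc)
  cube <- load_surface(pc)
  ctr <- colMeans(cube$vertices)
  expect_true(all(rowSums(cube$orientations *
                          sweep(cube$vertices, 2, ctr)) > 0))
})

test_that("the 10-20 montage has 19 scalp electrodes with the standard geometry", {
  el <- standard_montage("10-20", 92)
  expect_length(el$labels, 19)
  expect_false(anyDuplicated(el$labels) > 0)
  expect_lt(max(abs(sqrt(rowSums(el$positions^2)) - 92)), 1e-6)
  expect_equal(el$positions[el$labels == "Cz", ], c(0, 0, 92),
               tolerance = 1e-9)
  # left/right homologs mirror in x
  pairs <- list(c("Fp1", "Fp2"), c("F3", "F4"), c("F7", "F8"), c("C3", "C4"),
                c("T3", "T4"), c("T5", "T6"), c("P3", "P4"), c("O1", "O2"))
  for (pr in pairs) {
    l <- el$positions[el$labels == pr[1], ]
    r <- el$positions[el$labels == pr[2], ]
    expect_equal(l * c(-1, 1, 1), r, tolerance = 1e-6)
  }
  expect_error(standard_montage("10-5"), "supported",
               class = "ezloc_parameter_error")
})

test_that("electrode TSV round trip", {
  el <- standard_montage("10-20", 88)
  p <- file.path(tempdir(), "elec.tsv")
  write_electrodes(el, p)
  r <- read_electrodes(p)
  expect_identical(r$labels, el$labels)
  expect_equal(r$positions, el$positions, tolerance = 1e-6)
})

test_that("three-shell sphere leadfield: linearity, reference, physics", {
  fx <- esi_fixture()
  lf <- fx$lf
  expect_lt(max(abs(colSums(lf$gain))), 1e-9)   # average reference
  expect_true(all(is.finite(lf$gain)))

  # linearity in the dipole moment: scaling orientations scales potentials
  src3 <- fx$src
  src3$orientations <- src3$orientations * 3
  lf3 <- leadfield_sphere3(src3, fx$elec, c(79, 82, 88),
                           c(0.33, 0.0042, 0.33))
  expect_equal(lf3$gain, 3 * lf$gain, tolerance = 1e-12)

  # superficial source beats a colocated-direction deep source
  elec <- fx$elec
  sup <- make_sphere_source_space(1, 70)
  deep <- make_sphere_source_space(1, 35)
  g_sup <- leadfield_sphere3(sup, elec)$gain
  g_deep <- leadfield_sphere3(deep, elec)$gain
  expect_gt(max(abs(g_sup[, 1])), max(abs(g_deep[, 1])))

  expect_error(leadfield_sphere3(make_sphere_source_space(1, 85), elec),
               "innermost", class = "ezloc_geometry_error")
})

test_that("equal-conductivity series matches the homogeneous closed form", {
  fx <- esi_fixture()
  edir <- fx$elec$positions / sqrt(rowSums(fx$elec$positions^2))
  series <- getFromNamespace("sphere_potential_series", "ezloc")
  closed <- getFromNamespace("sphere_potential_homogeneous", "ezloc")
  Vs <- series(fx$src$vertices, fx$src$orientations, edir,
               c(79, 82, 88) / 88, c(0.33, 0.33, 0.33), 88)
  Vh <- closed(fx$src$vertices, fx$src$orientations, edir, 88, 0.33)
  expect_lt(max(abs(Vs - Vh)) / max(abs(Vh)), 1e-6)
})

test_that("sphere leadfield is continuous in source position", {
  elec <- standard_montage("10-20", 88)
  base <- list(vertices = matrix(c(30, 20, 25), 1),
               orientations = matrix(c(0, 0, 1), 1))
  shift <- base
  shift$vertices <- base$vertices + c(0.05, 0, 0)
  g1 <- leadfield_sphere3(structure(base, class = "source_space"), elec)$gain
  g2 <- leadfield_sphere3(structure(shift, class = "source_space"), elec)$gain
  expect_lt(max(abs(g1 - g2)) / max(abs(g1)), 0.01)
})

test_that("leadfield binary cache round-trips with its sidecar", {
  fx <- esi_fixture()
  p <- file.path(tempdir(), "lf.bin")
  write_leadfield(fx$lf, p)
  r <- read_leadfield(p)
  expect_equal(r$gain, fx$lf$gain, tolerance = 0)
  expect_identical(r$labels, fx$lf$labels)
  expect_identical(r$model, "sphere3")
})
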