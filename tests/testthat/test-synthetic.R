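# Ground-truth generator: phantoms, SPECT pairs, EEG simulation, bundles.

test_that("phantom head: geometric brain-mask oracle and determinism", {
  h <- make_phantom_head(c(48L, 48L, 48L), 2.5, seed = 3,
                         brain_radius_mm = 45, head_radius_mm = 52)
  # brute-force geometric count
  w <- getFromNamespace("grid_world_coords", "ezloc")(h$mri)
  want <- sum(sqrt(colSums(w^2)) <= 45)
  expect_equal(sum(h$brain$data), want)
  # brain strictly inside the head extent
  expect_true(all(h$mri$data[h$brain$data] > 0))
  head_ext <- h$mri$data > 0
  expect_true(all(head_ext[h$brain$data]))
  expect_gt(sum(head_ext), sum(h$brain$data))

  h2 <- make_phantom_head(c(48L, 48L, 48L), 2.5, seed = 3,
                          brain_radius_mm = 45, head_radius_mm = 52)
  expect_identical(h$mri$data, h2$mri$data)
  expect_error(make_phantom_head(c(16L, 16L, 16L)),
               class = "ezloc_parameter_error")
})

test_that("noise-free SPECT pair has the exact implanted ratio", {
  spec <- scenario_spec("focal", seed = 1, noise_sd = 0, session_sd = 0,
                        increase = 0.2)
  h <- make_phantom_head(spec$shape, spec$voxel_mm, seed = spec$seed,
                         brain_radius_mm = spec$brain_radius_mm,
                         head_radius_mm = spec$scalp_radius_mm)
  pair <- make_spect_pair(h, spec)
  ratio <- pair$ictal$data / pmax(pair$interictal$data, 1e-9)
  inside <- pair$blob$data & h$brain$data
  outside <- !pair$blob$data & h$brain$data
  expect_true(all(abs(ratio[inside] - 1.2) < 1e-9))
  expect_true(all(abs(ratio[outside] - 1) < 1e-9))
  # blob stays inside the brain
  expect_true(all(h$brain$data[pair$blob$data]))
  # out-of-brain blob center is refused
  expect_error(make_spect_pair(h, spec, blob_centers = c(0, 0, 70)),
               class = "ezloc_geometry_error")
})

test_that("null scenario (no hyperperfusion) yields a near-null z-map", {
  spec <- scenario_spec("focal", seed = 4, increase = 0, noise_sd = 0.05)
  h <- make_phantom_head(spec$shape, spec$voxel_mm, seed = spec$seed,
                         brain_radius_mm = spec$brain_radius_mm,
                         head_radius_mm = spec$scalp_radius_mm)
  pair <- make_spect_pair(h, spec)
  id <- list(interictal_to_ictal = diag(4), ictal_to_mri = diag(4))
  res <- run_siscom(pair$ictal, pair$interictal, h$mri, h$brain,
                    transforms = id)
  frac <- mean(abs(res$zmap$zvol$data[res$zmap$mask$data]) >= 2)
  # smoothing correlates voxels, but the suprathreshold fraction stays
  # within the same order as the Gaussian tail (P(|z|>=2) ~ 4.6%)
  expect_lt(frac, 0.10)
})

test_that("EEG simulation: noiseless limit, SNR calibration, determinism", {
  fx <- esi_fixture()
  sim0 <- simulate_eeg(fx$src, fx$lf, 100L, snr_db = Inf, seed = 1)
  expect_equal(sim0$eeg$data, fx$lf$gain %*% sim0$J_true, tolerance = 1e-12)
  # currents live only on the diffusion patch around the active vertex
  nz <- which(rowSums(sim0$J_true^2) > 0)
  expect_true(all(graph_rings(fx$src, 100L, nz) <= 3L))

  snrs <- sapply(1:20, function(s) {
    sim <- simulate_eeg(fx$src, fx$lf, 100L, snr_db = 12, seed = s)
    sig <- fx$lf$gain %*% sim$J_true
    noise <- sim$eeg$data - sig
    10 * log10(mean(sig^2) / mean(noise^2))
  })
  expect_true(all(abs(snrs - 12) < 0.5))

  sim_a <- simulate_eeg(fx$src, fx$lf, 100L, snr_db = 10, seed = 5)
  sim_b <- simulate_eeg(fx$src, fx$lf, 100L, snr_db = 10, seed = 5)
  expect_identical(sim_a$eeg$data, sim_b$eeg$data)
  expect_error(simulate_eeg(fx$src, fx$lf, integer(0)),
               class = "ezloc_parameter_error")
})

test_that("bundles are written with reproducible checksums and scenario geometry", {
  spec <- scenario_spec("focal", seed = 6)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  b1 <- make_dataset(spec, d1)
  b2 <- make_dataset(spec, d2)
  expect_identical(unname(unlist(b1$manifest$files)),
                   unname(unlist(b2$manifest$files)))
  expect_true(all(file.exists(b1$paths)))

  # focal: blob center within 5 mm of the active-patch centroid
  src_pos <- b1$source_space$vertices[b1$active_vertices[[1]], ]
  expect_lt(sqrt(sum((b1$truth$blob_centers[1, ] - src_pos)^2)), 5)
  expect_false(is.null(b1$resection))

  # reading the bundle back reproduces the volumes
  rb <- read_bundle(d1)
  expect_equal(rb$ictal$data, b1$ictal$data, tolerance = 1e-6)
  expect_equal(rb$leadfield$gain, b1$leadfield$gain, tolerance = 0)
  expect_identical(rb$eeg$labels, b1$eeg$labels)
})

test_that("multifocal bundles carry at least two disjoint blob components", {
  b <- fixture("bundle_multi", make_dataset(scenario_spec("multifocal", seed = 2)))
  lab <- oracle_label_components(b$blob_mask$data)
  expect_gte(max(lab), 2L)
  expect_null(b$resection)
  expect_length(b$active_vertices, 2L)
})

test_that("discordant bundles separate blob, source and resection", {
  b <- fixture("bundle_disc", make_dataset(scenario_spec("discordant", seed = 3)))
  src_pos <- b$source_space$vertices[b$active_vertices[[1]], ]
  blob <- b$truth$blob_centers[1, ]
  expect_gt(sqrt(sum((blob - src_pos)^2)), 20)      # blob well posterior
  # resection contains neither the blob center nor the source position
  w <- getFromNamespace("grid_world_coords", "ezloc")(b$mri)
  res_vox <- which(b$resection$data)
  dmin <- function(pt) min(sqrt(colSums((w[, res_vox] - pt)^2)))
  expect_gt(dmin(blob), 10)
  expect_gt(dmin(src_pos), 10)
})
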