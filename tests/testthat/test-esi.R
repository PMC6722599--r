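# Inverse solution: referencing, prior libraries, MSP/ReML, SISCOM priors,
# EZ maps.

test_that("average referencing is exact and idempotent", {
  set.seed(1)
  eeg <- eeg_epoch(matrix(rnorm(19 * 50), 19), 200,
                   standard_montage("10-20")$labels)
  ar <- average_reference(eeg)
  # independent per-sample mean loop
  for (t in c(1, 25, 50))
    expect_lt(abs(sum(ar$data[, t]) / 19), 1e-9)
  expect_equal(average_reference(ar)$data, ar$data, tolerance = 1e-12)
  off <- eeg
  off$data <- eeg$data + 42
  expect_equal(average_reference(off)$data, ar$data, tolerance = 1e-9)
})

test_that("EEG TSV round trip preserves labels and data", {
  set.seed(2)
  eeg <- eeg_epoch(matrix(rnorm(19 * 30), 19), 200,
                   standard_montage("10-20")$labels)
  p <- file.path(tempdir(), "eeg.tsv")
  write_eeg_tsv(eeg, p)
  r <- read_eeg_tsv(p, 200)
  expect_identical(r$labels, eeg$labels)
  expect_equal(r$data, eeg$data, tolerance = 1e-12)
})

test_that("patch library: delta limit, peak at center, ring-wise decay", {
  src <- make_sphere_source_space(2, 60)
  lib0 <- build_patch_library(src, 16L, smoothness = 0L, seed = 3)
  for (i in seq_along(lib0$profiles)) {
    pr <- lib0$profiles[[i]]
    expect_equal(pr[lib0$seeds[[i]]], 1)
    expect_equal(sum(pr > 0), 1L)
  }
  lib <- build_patch_library(src, 16L, smoothness = 3L, seed = 3)
  for (i in seq_along(lib$profiles)) {
    pr <- lib$profiles[[i]]
    ctr <- lib$seeds[[i]]
    expect_equal(which.max(pr), ctr)
    expect_true(all(pr >= 0) && max(pr) == 1)
    rings <- graph_rings(src, ctr)
    ringmax <- tapply(pr, rings, max)
    expect_true(all(diff(ringmax) <= 1e-12))
  }
  expect_error(build_patch_library(src, 1000L), class = "ezloc_parameter_error")
})

test_that("farthest-point centers cover the mesh without holes", {
  src <- make_sphere_source_space(3, 60)
  lib <- build_patch_library(src, 256L, smoothness = 3L, seed = 1)
  centers <- unlist(lib$seeds)
  dist_to_center <- graph_rings(src, centers)
  expect_lte(max(dist_to_center), 2L)
})

test_that("siscom prior components map clusters onto the cortex", {
  src <- make_sphere_source_space(2, 60)
  shape <- c(20L, 20L, 20L)
  aff <- std_affine(7, shape)  # coarse grid covering the sphere
  z <- array(0, shape)
  # cluster A around a vertex position; cluster B on the opposite side
  va <- src$vertices[1, ]; vb <- -va
  ijk_a <- round(solve(aff) %*% c(va, 1))[1:3] + 1
  ijk_b <- round(solve(aff) %*% c(vb, 1))[1:3] + 1
  z[ijk_a[1] + (-1:1), ijk_a[2] + (-1:1), ijk_a[3] + (-1:1)] <- 3
  z[ijk_b[1] + (-1:1), ijk_b[2] + (-1:1), ijk_b[3] + (-1:1)] <- 3
  zm <- structure(list(zvol = as_volume(z, aff),
                       mask = as_mask(array(TRUE, shape), aff),
                       mean_diff = 0, sd_diff = 1), class = "zscore_map")
  cs <- threshold_clusters(zm, 2, 1L)
  expect_length(cs$clusters, 2)
  lib <- siscom_prior_components(cs, src, max_dist_mm = 12)
  expect_length(lib$profiles, 2)          # one component per cluster
  expect_true(all(lib$tags == "siscom"))
  # a voxel exactly at vertex 1 seeds vertex 1
  expect_true(1L %in% unlist(lib$seeds))

  # cluster entirely beyond reach: no component, warning names the cluster
  deep <- array(0, shape)
  deep[10:11, 10:11, 10:11] <- 3          # near the center, far from r=60
  zmd <- structure(list(zvol = as_volume(deep, aff), mask = zm$mask,
                        mean_diff = 0, sd_diff = 1), class = "zscore_map")
  csd <- threshold_clusters(zmd, 2, 1L)
  expect_warning(libd <- siscom_prior_components(csd, src, max_dist_mm = 10),
                 "cluster 1", class = "ezloc_prior_warning")
  expect_length(libd$profiles, 0)
})

test_that("MSP recovers a colocated patch and prunes the library", {
  fx <- esi_fixture()
  center <- fx$lib$seeds[[10]]
  sim <- sim_focal_epoch(center, snr_db = 20, seed = 7)
  res <- invert_msp(sim$eeg, fx$lf, fx$lib)
  expect_true(res$converged)
  # free energy is non-decreasing within tolerance
  tr <- res$free_energy_trace
  expect_true(all(diff(tr) >= -1e-6 * pmax(abs(tr[-1]), 1)))
  # peak within 2 adjacency rings
  pk <- which.max(rowMeans(res$J^2))
  expect_lte(graph_rings(fx$src, center, pk), 2L)
  # ARD sparsity: < 10% of components survive at 20 dB
  expect_lt(length(res$active_components), 0.10 * length(fx$lib$tags))
})

test_that("pure-noise data yield little posterior power vs an active source", {
  fx <- esi_fixture()
  set.seed(11)
  noise_eeg <- eeg_epoch(matrix(rnorm(19 * 200, sd = 1), 19), 200,
                         fx$elec$labels)
  sim <- sim_focal_epoch(fx$lib$seeds[[20]], snr_db = 10, seed = 11)
  # match the sensor scale so powers are comparable
  scale <- sqrt(mean(sim$eeg$data^2))
  noise_scaled <- noise_eeg
  noise_scaled$data <- noise_scaled$data / sqrt(mean(noise_scaled$data^2)) *
    scale
  res_noise <- invert_msp(noise_scaled, fx$lf, fx$lib)
  res_sig <- invert_msp(sim$eeg, fx$lf, fx$lib)
  expect_lt(sum(res_noise$J^2), 0.10 * sum(res_sig$J^2))
})

test_that("channel matching is by label, not order", {
  fx <- esi_fixture()
  center <- fx$lib$seeds[[30]]
  sim <- sim_focal_epoch(center, snr_db = 20, seed = 3)
  perm <- sample(19)
  eeg_perm <- eeg_epoch(sim$eeg$data[perm, ], sim$eeg$srate,
                        sim$eeg$labels[perm])
  res1 <- invert_msp(sim$eeg, fx$lf, fx$lib)
  res2 <- invert_msp(eeg_perm, fx$lf, fx$lib)
  expect_equal(res1$J, res2$J, tolerance = 1e-9)
})

test_that("missing channels raise an informative error", {
  fx <- esi_fixture()
  sim <- sim_focal_epoch(5L, snr_db = 20, seed = 4)
  bad <- eeg_epoch(sim$eeg$data[-1, ], 200, sim$eeg$labels[-1])
  expect_error(invert_msp(bad, fx$lf, fx$lib), "Fp1",
               class = "ezloc_parameter_error")
})

test_that("posterior currents are linear in the data at fixed hyperparameters", {
  fx <- esi_fixture()
  sim <- sim_focal_epoch(fx$lib$seeds[[40]], snr_db = 20, seed = 5)
  res1 <- invert_msp(sim$eeg, fx$lf, fx$lib)
  eeg2 <- sim$eeg
  eeg2$data <- 2 * eeg2$data
  res2 <- invert_msp(eeg2, fx$lf, fx$lib)
  # scaling the epoch scales covariance by 4 and hyperparameters follow;
  # the posterior map is scale-equivariant, so J doubles
  expect_equal(res2$J, 2 * res1$J, tolerance = 0.05)
})

test_that("empty SISCOM augmentation reproduces plain MSP exactly", {
  fx <- esi_fixture()
  sim <- sim_focal_epoch(fx$lib$seeds[[50]], snr_db = 15, seed = 6)
  res_plain <- invert_msp(sim$eeg, fx$lf, fx$lib)
  res_aug <- invert_with_siscom_prior(sim$eeg, fx$lf, fx$lib, NULL)
  expect_identical(res_plain$J, res_aug$J)
  empty_lib <- combine_priors(fx$lib)
  empty_lib$profiles <- list(); empty_lib$tags <- character(0)
  empty_lib$seeds <- list()
  res_aug2 <- invert_with_siscom_prior(sim$eeg, fx$lf, fx$lib, empty_lib)
  expect_identical(res_plain$J, res_aug2$J)
})

test_that("a colocated SISCOM prior does not hurt; a wrong one is out-voted", {
  fx <- esi_fixture()
  center <- fx$lib$seeds[[60]]
  prof <- getFromNamespace("diffusion_profile", "ezloc")(fx$src, center, 3L)
  good <- structure(list(profiles = list(prof), seeds = list(center),
                         tags = "siscom"), class = "prior_library")
  errs <- sapply(1:8, function(s) {
    sim <- sim_focal_epoch(center, snr_db = 10, seed = 100 + s)
    r0 <- invert_msp(sim$eeg, fx$lf, fx$lib)
    r1 <- invert_with_siscom_prior(sim$eeg, fx$lf, fx$lib, good)
    c(plain = graph_rings(fx$src, center, which.max(rowMeans(r0$J^2))),
      prior = graph_rings(fx$src, center, which.max(rowMeans(r1$J^2))))
  })
  expect_lte(median(errs["prior", ]), median(errs["plain", ]))

  # contralateral prior at high SNR: true-side patches keep the weight
  far <- which.max(graph_rings(fx$src, center))
  bad_prof <- getFromNamespace("diffusion_profile", "ezloc")(fx$src, far, 3L)
  bad <- structure(list(profiles = list(bad_prof), seeds = list(far),
                        tags = "siscom"), class = "prior_library")
  sim <- sim_focal_epoch(center, snr_db = 20, seed = 9)
  r2 <- invert_with_siscom_prior(sim$eeg, fx$lf, fx$lib, bad)
  w <- r2$hyperparameters[-1]
  ipsi <- sum(w[r2$lib_tags == "patch"])
  expect_gt(ipsi, unname(r2$siscom_weights))
})

test_that("EZ map thresholding and rendering follow the declared rules", {
  fx <- esi_fixture()
  mri <- fixture("bundle42", make_dataset(scenario_spec("focal", seed = 42)))$mri
  center <- fx$lib$seeds[[10]]
  sim <- sim_focal_epoch(center, snr_db = 20, seed = 7)
  res <- invert_msp(sim$eeg, fx$lf, fx$lib)

  ez1 <- source_to_ez_map(res, fx$src, mri, frac = 1)
  pw <- rowMeans(res$J^2)
  expect_identical(ez1$vertices, which(pw == max(pw)))

  ez0 <- source_to_ez_map(res, fx$src, mri, frac = 1e-12)
  expect_identical(ez0$vertices, which(pw > 0))

  # rendered voxel count equals the brute-force distance count
  res_single <- res
  res_single$J <- matrix(0, nrow(res$J), ncol(res$J))
  res_single$J[center, ] <- 1
  ez <- source_to_ez_map(res_single, fx$src, mri, frac = 0.5,
                         render_radius_mm = 4)
  w <- getFromNamespace("grid_world_coords", "ezloc")(mri)
  want <- sum(colSums((w - fx$src$vertices[center, ])^2) <= 16)
  expect_equal(sum(ez$mask$data), want)

  res_zero <- res
  res_zero$J[] <- 0
  expect_warning(ezz <- source_to_ez_map(res_zero, fx$src, mri),
                 class = "ezloc_degenerate_result_warning")
  expect_equal(sum(ezz$mask$data), 0)
  expect_error(source_to_ez_map(res, fx$src, mri, frac = 0),
               class = "ezloc_parameter_error")
})
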