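# SISCOM stages: normalization, subtraction, smoothing, z-scoring,
# clustering, and the assembled pipeline.

test_that("global normalization forces the brain mean to the target", {
  aff <- std_affine(2, c(10L, 10L, 10L))
  m <- rand_mask(c(10L, 10L, 10L), seed = 1, p = 0.6)
  u <- as_volume(array(7, c(10, 10, 10)), aff)
  n <- normalize_global(u, m)
  expect_true(all(abs(n$data[m$data] - 100) < 1e-9))

  v <- rand_volume(c(10L, 10L, 10L), seed = 2)
  v$data <- abs(v$data) + 0.5
  n2 <- normalize_global(v, m)
  # independent loop-oracle mean
  s <- 0; k <- 0
  for (i in seq_along(n2$data)) if (m$data[i]) { s <- s + n2$data[i]; k <- k + 1 }
  expect_equal(s / k, 100, tolerance = 1e-9)
  expect_equal(normalize_global(n2, m)$data, n2$data, tolerance = 1e-9)

  zero <- as_volume(array(0, c(10, 10, 10)), aff)
  expect_error(normalize_global(zero, m), "nonpositive",
               class = "ezloc_degenerate_input_error")
})

test_that("subtraction is exact voxelwise arithmetic", {
  a <- rand_volume(seed = 3); b <- rand_volume(seed = 4)
  expect_true(all(subtract_volumes(a, a)$data == 0))
  zero <- a; zero$data[] <- 0
  expect_equal(subtract_volumes(a, zero)$data, a$data)
  expect_equal(subtract_volumes(a, b)$data[3, 4, 5],
               a$data[3, 4, 5] - b$data[3, 4, 5])
})

test_that("gaussian smoothing: mass preservation, constants, impulse FWHM", {
  expect_equal(12 / (2 * sqrt(2 * log(2))), 5.0955, tolerance = 1e-4)

  shape <- c(61L, 61L, 61L)
  aff <- std_affine(1, shape)
  const <- as_volume(array(2.5, shape), aff)
  sm <- smooth_gaussian(const, 6)
  expect_equal(sm$data[25:37, 25:37, 25:37],
               array(2.5, c(13, 13, 13)), tolerance = 1e-9)

  imp <- as_volume(array(0, shape), aff)
  imp$data[31, 31, 31] <- 1
  sm12 <- smooth_gaussian(imp, 12)
  expect_equal(sum(sm12$data), 1, tolerance = 1e-6)  # mass preserved
  fwhm <- oracle_impulse_fwhm(sm12$data[, 31, 31], spacing_mm = 1)
  expect_lt(abs(fwhm - 12) / 12, 0.05)

  expect_error(smooth_gaussian(imp, 0), class = "ezloc_parameter_error")
})

test_that("z-scoring follows the population-SD convention", {
  aff <- std_affine(1, c(4L, 4L, 4L))
  d <- array(0, c(4, 4, 4)); d[1, 1, 1] <- 1; d[2, 1, 1] <- 3
  m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE
  zm <- zscore_map(as_volume(d, aff), as_mask(m, aff))
  expect_equal(zm$mean_diff, 2)
  expect_equal(zm$sd_diff, 1)
  expect_equal(zm$zvol$data[1, 1, 1], -1)
  expect_equal(zm$zvol$data[2, 1, 1], 1)
  expect_true(all(zm$zvol$data[!m] == 0))

  # standardization identity + brute-force oracle on a 20^3 mask
  diff <- rand_volume(c(20L, 20L, 20L), seed = 5)
  mask <- rand_mask(c(20L, 20L, 20L), seed = 6, p = 0.7)
  zm2 <- zscore_map(diff, mask)
  zv <- zm2$zvol$data[mask$data]
  expect_equal(mean(zv), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(zv^2)), 1, tolerance = 1e-6)
  expect_equal(zm2$zvol$data, oracle_zscores(diff$data, mask$data),
               tolerance = 1e-12)

  same <- as_volume(array(5, c(20, 20, 20)), diff$affine)
  expect_error(zscore_map(subtract_volumes(same, same), mask),
               "zero SD", class = "ezloc_degenerate_input_error")
})

test_that("cluster extraction matches an independent flood-fill oracle", {
  shape <- c(12L, 12L, 12L)
  aff <- std_affine(2, shape)
  all_mask <- as_mask(array(TRUE, shape), aff)

  # all-subthreshold map gives an empty set
  z0 <- structure(list(zvol = as_volume(array(0.5, shape), aff),
                       mask = all_mask, mean_diff = 0, sd_diff = 1),
                  class = "zscore_map")
  expect_length(threshold_clusters(z0, 2, 1L)$clusters, 0)

  # 50 random thresholded images: exact voxel-set equality per component
  for (s in 1:50) {
    set.seed(100 + s)
    z <- array(rnorm(prod(shape), sd = 1.4), shape)
    zm <- structure(list(zvol = as_volume(z, aff), mask = all_mask,
                         mean_diff = 0, sd_diff = 1), class = "zscore_map")
    cs <- threshold_clusters(zm, 2, 1L)
    lab <- oracle_label_components(z >= 2)
    ncomp <- max(lab)
    expect_length(cs$clusters, ncomp)
    got <- lapply(cs$clusters, function(cl) sort(cl$voxels))
    want <- lapply(seq_len(ncomp), function(i) sort(which(lab == i)))
    # order-insensitive exact match
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("two separated blobs give two clusters with exact counts and sizes filter", {
  shape <- c(16L, 16L, 16L)
  aff <- std_affine(2, shape)
  z <- array(0, shape)
  z[3:5, 3:5, 3:5] <- 3       # 27 voxels
  z[10:13, 10:12, 10:11] <- 4 # 24 voxels
  zm <- structure(list(zvol = as_volume(z, aff),
                       mask = as_mask(array(TRUE, shape), aff),
                       mean_diff = 0, sd_diff = 1), class = "zscore_map")
  cs <- threshold_clusters(zm, 2, 1L)
  expect_length(cs$clusters, 2)
  expect_setequal(vapply(cs$clusters, `[[`, 0L, "size"), c(27L, 24L))
  expect_equal(cs$clusters[[1]]$peak_z, 4)  # sorted by descending peak
  expect_length(threshold_clusters(zm, 2, 25L)$clusters, 1)

  # blob clipped by the mask edge: size equals blob-within-mask count
  mask_half <- array(FALSE, shape); mask_half[1:4, , ] <- TRUE
  zm2 <- structure(list(zvol = as_volume(z, aff),
                        mask = as_mask(mask_half, aff),
                        mean_diff = 0, sd_diff = 1), class = "zscore_map")
  cs2 <- threshold_clusters(zm2, 2, 1L)
  expect_length(cs2$clusters, 1)
  expect_equal(cs2$clusters[[1]]$size, sum(z >= 2 & mask_half))
})

test_that("raising the z threshold never increases suprathreshold voxel count", {
  shape <- c(14L, 14L, 14L)
  aff <- std_affine(2, shape)
  set.seed(7)
  z <- array(rnorm(prod(shape), sd = 1.5), shape)
  zm <- structure(list(zvol = as_volume(z, aff),
                       mask = as_mask(array(TRUE, shape), aff),
                       mean_diff = 0, sd_diff = 1), class = "zscore_map")
  tot <- vapply(c(1, 1.5, 2, 2.5, 3), function(th)
    sum(vapply(threshold_clusters(zm, th, 1L)$clusters, `[[`, 0L, "size")), 0)
  expect_true(all(diff(tot) <= 0))
})

test_that("run_siscom recovers an implanted blob (known geometry)", {
  spec <- scenario_spec("focal", seed = 42)
  b <- fixture("bundle42", make_dataset(spec))
  id <- list(interictal_to_ictal = diag(4), ictal_to_mri = diag(4))
  res <- run_siscom(b$ictal, b$interictal, b$mri, b$brain_mask,
                    transforms = id)
  # z-map standardization identity on its native grid
  zv <- res$zmap$zvol$data[res$zmap$mask$data]
  expect_equal(mean(zv), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(zv^2)), 1, tolerance = 1e-6)
  # top cluster centroid within 2 voxels (4 mm) of the blob center
  expect_gt(length(res$clusters$clusters), 0)
  centroid <- res$clusters$clusters[[1]]$centroid_mm
  expect_lt(sqrt(sum((centroid - b$truth$blob_centers[1, ])^2)), 4)  # 2 voxels
  # determinism
  res2 <- run_siscom(b$ictal, b$interictal, b$mri, b$brain_mask,
                     transforms = id)
  expect_identical(res$zmap_mri$data, res2$zmap_mri$data)
})

test_that("identical noise-free scans raise the degenerate-SD error", {
  h <- make_phantom_head(c(32L, 32L, 32L), 3, seed = 2, brain_radius_mm = 40,
                         head_radius_mm = 45)
  id <- list(interictal_to_ictal = diag(4), ictal_to_mri = diag(4))
  expect_error(
    run_siscom(h$mri, h$mri, h$mri, h$brain, transforms = id),
    "zero SD", class = "ezloc_degenerate_input_error")
})

test_that("a 3-mm interictal shift is absorbed by registration (Dice >= 0.6)", {
  spec <- scenario_spec("focal", seed = 42, noise_sd = 0.05)
  b <- fixture("bundle42", make_dataset(spec))
  shifted <- resample_to(b$interictal, b$interictal,
                         rigid_transform(translation = c(3, 0, 0)))
  res <- run_siscom(b$ictal, shifted, b$mri, b$brain_mask)
  # blob recovery = the top cluster (the hyperperfusion hypothesis)
  top <- res$clusters$clusters[[1]]
  got <- array(FALSE, dim(b$mri$data))
  got[top$voxels] <- TRUE
  truth <- b$blob_mask$data
  dice <- 2 * sum(got & truth) / (sum(got) + sum(truth))
  expect_gte(dice, 0.6)
})
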