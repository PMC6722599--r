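# SISCOM: subtraction ictal SPECT co-registered to MRI.
#
# Stage order follows the classical subtraction methodology: co-register the
# interictal scan to the ictal scan, mask out extracerebral activity,
# normalize each scan to a common global brain mean, subtract, smooth the
# difference with a 12-mm FWHM Gaussian, z-score against all brain voxels,
# co-register to the MRI, and extract suprathreshold clusters at z >= 2.

#' Global-count normalization
#'
#' Scales a (masked) perfusion volume so its mean over the brain mask equals
#' `target` (default 100, the common SPECT convention; any positive constant
#' is equivalent after z-scoring). Zeros outside the mask are preserved.
#'
#' @param vol `volume3d`.
#' @param mask Brain `binary_mask` on the same grid.
#' @param target Desired brain mean.
#' @return Normalized `volume3d`.
#' @export
normalize_global <- function(vol, mask, target = 100) {
  if (!same_grid(vol, mask))
    stop_ezloc("volume and mask grids differ", "ezloc_alignment_error")
  m <- mean(vol$data[mask$data])
  if (!is.finite(m) || m <= 0)
    stop_ezloc(sprintf("nonpositive brain mean (%g); cannot normalize", m),
               "ezloc_degenerate_input_error")
  out <- vol
  out$data <- vol$data * (target / m)
  out
}

#' Voxelwise subtraction (ictal minus interictal)
#'
#' @param ictal_n,interictal_n Normalized `volume3d` pair on one grid.
#' @return Difference `volume3d`.
#' @export
subtract_volumes <- function(ictal_n, interictal_n) {
  if (!same_grid(ictal_n, interictal_n))
    stop_ezloc("ictal and interictal grids differ; co-register first",
               "ezloc_alignment_error")
  out <- ictal_n
  out$data <- ictal_n$data - interictal_n$data
  out
}

# 1-D gaussian kernel, unit sum, truncated at 4 sigma.
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox < 1e-6) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable convolution along one array axis via banded-matrix product.
convolve_axis <- function(data, kernel, axis) {
  if (length(kernel) == 1L) return(data)
  d <- dim(data)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    src <- idx + o
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kernel[o + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(data, perm)
  m <- matrix(a, nrow = n)
  out <- K %*% m
  a2 <- array(out, dim = d[perm])
  aperm(a2, order(perm))
}

#' 3-D Gaussian smoothing by FWHM
#'
#' Separable Gaussian smoothing with per-axis sigma (in voxel units)
#' `fwhm / (2 * sqrt(2 * log(2))) / voxel_size`, honoring anisotropic
#' voxels. The kernel is unit-sum (zero-padded boundaries), so total image
#' mass is preserved for interior-supported images.
#'
#' @param vol `volume3d`.
#' @param fwhm_mm Full width at half maximum in mm (> 0).
#' @return Smoothed `volume3d`.
#' @export
smooth_gaussian <- function(vol, fwhm_mm) {
  assert_scalar_num(fwhm_mm, "fwhm_mm", positive = TRUE)
  sig_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxel_sizes(vol)
  out <- vol$data
  for (ax in 1:3)
    out <- convolve_axis(out, gauss_kernel_1d(sig_mm / vs[ax]), ax)
  v <- vol
  v$data <- out
  v
}

#' Z-score a difference image over the brain mask
#'
#' Standardizes the difference image by the mean and population SD of all
#' brain voxels; outside-mask voxels are set to 0 and excluded from every
#' statistic.
#'
#' @param diff Difference `volume3d`.
#' @param mask Brain `binary_mask` on the same grid.
#' @return A `zscore_map`: list with `zvol` (`volume3d`), `mask`,
#'   `mean_diff`, `sd_diff`.
#' @export
zscore_map <- function(diff, mask) {
  if (!same_grid(diff, mask))
    stop_ezloc("difference and mask grids differ", "ezloc_alignment_error")
  vals <- diff$data[mask$data]
  if (length(vals) == 0)
    stop_ezloc("empty brain mask", "ezloc_degenerate_input_error")
  mu <- mean(vals)
  sd_pop <- sqrt(mean((vals - mu)^2))
  if (!(sd_pop > 0))
    stop_ezloc("zero SD of differences over the brain mask (identical scans?); z-scoring undefined",
               "ezloc_degenerate_input_error")
  z <- array(0, dim(diff$data))
  z[mask$data] <- (vals - mu) / sd_pop
  structure(list(zvol = as_volume(z, diff$affine), mask = mask,
                 mean_diff = mu, sd_diff = sd_pop),
            class = "zscore_map")
}

#' @export
print.zscore_map <- function(x, ...) {
  cat(sprintf("<zscore_map> mean_diff=%.4g sd_diff=%.4g, %d brain voxels\n",
              x$mean_diff, x$sd_diff, sum(x$mask$data)))
  invisible(x)
}

# 26-neighborhood offsets (0-based index deltas).
neighbor_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  as.matrix(g)
}

# Label connected components of a logical array (26-connectivity) by BFS.
label_components <- function(bin) {
  d <- dim(bin)
  lab <- array(0L, d)
  offs <- neighbor_offsets_26()
  lin_off <- offs[, 1] + d[1] * offs[, 2] + d[1] * d[2] * offs[, 3]
  which_on <- which(bin)
  cur <- 0L
  # precompute voxel coords for border checks
  for (start in which_on) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      # expand all frontier voxels at once
      i0 <- (q - 1L) %% d[1]
      j0 <- ((q - 1L) %/% d[1]) %% d[2]
      k0 <- (q - 1L) %/% (d[1] * d[2])
      for (o in seq_len(nrow(offs))) {
        ii <- i0 + offs[o, 1]; jj <- j0 + offs[o, 2]; kk <- k0 + offs[o, 3]
        ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
        nb <- q[ok] + lin_off[o]
        nb <- nb[bin[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Extract suprathreshold clusters from a z-map
#'
#' Connected components (26-neighborhood) of `{z >= z_threshold}` within
#' the brain mask, filtered by a minimum size and sorted by descending peak
#' z. An empty result is valid.
#'
#' @param zmap A `zscore_map`.
#' @param z_threshold Cluster-forming threshold (default 2).
#' @param min_size Minimum cluster size in voxels (>= 1).
#' @return A `cluster_set`: list with `clusters` (each has `voxels` — linear
#'   indices into the z array —, `size`, `peak_z`, `peak_mm`, `centroid_mm`),
#'   `threshold`, `connectivity`, and the source grid `affine`/`shape`.
#' @export
threshold_clusters <- function(zmap, z_threshold = 2, min_size = 10L) {
  stopifnot(inherits(zmap, "zscore_map"))
  if (min_size < 1L)
    stop_ezloc("min_size must be >= 1", "ezloc_parameter_error")
  z <- zmap$zvol$data
  bin <- (z >= z_threshold) & zmap$mask$data
  lab <- label_components(bin)
  ncomp <- max(lab)
  clusters <- list()
  d <- dim(z)
  aff <- zmap$zvol$affine
  if (ncomp > 0) {
    for (cid in seq_len(ncomp)) {
      vox <- which(lab == cid)
      if (length(vox) < min_size) next
      i <- (vox - 1L) %% d[1]
      j <- ((vox - 1L) %/% d[1]) %% d[2]
      k <- (vox - 1L) %/% (d[1] * d[2])
      world <- aff[1:3, 1:3] %*% rbind(i, j, k) + aff[1:3, 4]
      zi <- z[vox]
      pk <- which.max(zi)
      clusters[[length(clusters) + 1L]] <- list(
        voxels = vox, size = length(vox), peak_z = zi[pk],
        peak_mm = as.numeric(world[, pk]),
        centroid_mm = as.numeric(rowMeans(world)))
    }
    if (length(clusters))
      clusters <- clusters[order(vapply(clusters, `[[`, 0, "peak_z"),
                                 decreasing = TRUE)]
  }
  structure(list(clusters = clusters, threshold = z_threshold,
                 connectivity = 26L, min_size = as.integer(min_size),
                 affine = aff, shape = d),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) at z >= %g (26-connectivity)\n",
              length(x$clusters), x$threshold))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: %d voxels, peak z=%.2f at (%.1f, %.1f, %.1f) mm\n",
                i, cl$size, cl$peak_z, cl$peak_mm[1], cl$peak_mm[2],
                cl$peak_mm[3]))
  }
  invisible(x)
}

#' Keep only clusters whose peak reaches a stricter criterion
#'
#' Two-threshold cluster reporting, as customary for statistical maps:
#' cluster extent is defined at the cluster-forming threshold (z >= 2),
#' but only clusters whose peak z reaches `peak_z` are reported as
#' hyperperfusion foci. Weak diffuse clusters produced by inter-session
#' perfusion variability rarely peak far above the forming threshold.
#'
#' @param cs A `cluster_set`.
#' @param peak_z Minimum peak z for a cluster to count as a focus.
#' @return A `cluster_set` containing the qualifying clusters.
#' @export
filter_clusters <- function(cs, peak_z = 4) {
  out <- cs
  out$clusters <- Filter(function(cl) cl$peak_z >= peak_z, cs$clusters)
  out$peak_threshold <- peak_z
  out
}

#' Binary mask of all cluster voxels
#' @param cs A `cluster_set`.
#' @return `binary_mask` on the cluster grid.
#' @export
cluster_mask <- function(cs) {
  m <- array(FALSE, cs$shape)
  for (cl in cs$clusters) m[cl$voxels] <- TRUE
  as_mask(m, cs$affine)
}

#' Cluster table as a data frame
#' @param cs A `cluster_set`.
#' @return data.frame with id, size, peak_z and world-mm coordinates.
#' @export
cluster_table <- function(cs) {
  if (!length(cs$clusters))
    return(data.frame(id = integer(0), size = integer(0), peak_z = numeric(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0), centroid_x_mm = numeric(0),
                      centroid_y_mm = numeric(0), centroid_z_mm = numeric(0)))
  do.call(rbind, lapply(seq_along(cs$clusters), function(i) {
    cl <- cs$clusters[[i]]
    data.frame(id = i, size = cl$size, peak_z = cl$peak_z,
               peak_x_mm = cl$peak_mm[1], peak_y_mm = cl$peak_mm[2],
               peak_z_mm = cl$peak_mm[3], centroid_x_mm = cl$centroid_mm[1],
               centroid_y_mm = cl$centroid_mm[2],
               centroid_z_mm = cl$centroid_mm[3])
  }))
}

#' Run the full SISCOM pipeline
#'
#' Executes, in order: rigid registration of the interictal to the ictal
#' scan, brain masking of both, global-count normalization, subtraction,
#' Gaussian smoothing of the difference (default FWHM 12 mm), z-scoring
#' over brain voxels, rigid registration of the ictal scan to the MRI,
#' resampling of the z-map onto the MRI grid, and cluster extraction at the
#' z threshold (default 2). All intermediates are returned for audit.
#'
#' @param ictal,interictal Perfusion `volume3d` pair.
#' @param mri Anatomical `volume3d` defining the output grid.
#' @param brain_mask `binary_mask` on the MRI grid.
#' @param fwhm_mm Smoothing kernel FWHM (mm).
#' @param z_threshold Cluster-forming z threshold.
#' @param min_size Minimum cluster size (voxels).
#' @param norm_target Global normalization target mean.
#' @param transforms Optional list with known `interictal_to_ictal` and
#'   `ictal_to_mri` transforms (each a `rigid_transform` or 4x4 matrix);
#'   when supplied, registration is skipped (phantoms with known geometry).
#' @return A `siscom_result`: list with `zmap` (SPECT space), `zmap_mri`
#'   (`volume3d` on MRI grid), `clusters` (`cluster_set`, MRI grid),
#'   `transforms`, and intermediates.
#' @export
run_siscom <- function(ictal, interictal, mri, brain_mask, fwhm_mm = 12,
                       z_threshold = 2, min_size = 10L, norm_target = 100,
                       transforms = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ezloc(sprintf("[siscom:%s] %s", name, conditionMessage(e)),
                 class(e)[1])
    })
  }
  t_i2i <- transforms$interictal_to_ictal %||% NULL
  t_i2m <- transforms$ictal_to_mri %||% NULL
  if (is.null(t_i2i))
    t_i2i <- stage("register_interictal", register_rigid(interictal, ictal))
  if (is.null(t_i2m))
    t_i2m <- stage("register_ictal_mri", register_rigid(ictal, mri))

  # brain mask pulled onto the SPECT (ictal) grid through the estimated
  # ictal->MRI transform
  mask_spect <- stage("mask", resample_to(
    brain_mask, ictal, invert_transform(t_i2m)))
  inter_reg <- stage("resample_interictal",
                     resample_to(interictal, ictal, t_i2i))

  ictal_m <- stage("mask", apply_mask(ictal, mask_spect))
  inter_m <- stage("mask", apply_mask(inter_reg, mask_spect))
  ictal_n <- stage("normalize", normalize_global(ictal_m, mask_spect, norm_target))
  inter_n <- stage("normalize", normalize_global(inter_m, mask_spect, norm_target))
  diff <- stage("subtract", subtract_volumes(ictal_n, inter_n))
  diff_s <- stage("smooth", smooth_gaussian(diff, fwhm_mm))
  zmap <- stage("zscore", zscore_map(diff_s, mask_spect))

  zmap_mri <- stage("resample_zmap", resample_to(zmap$zvol, mri, t_i2m))
  zmap_mri_masked <- stage("mask_zmap", apply_mask(zmap_mri, brain_mask))
  zmap_on_mri <- structure(list(zvol = zmap_mri_masked, mask = brain_mask,
                                mean_diff = zmap$mean_diff,
                                sd_diff = zmap$sd_diff),
                           class = "zscore_map")
  clusters <- stage("clusters", threshold_clusters(zmap_on_mri, z_threshold,
                                                   min_size))
  structure(list(
    zmap = zmap, zmap_mri = zmap_mri_masked, clusters = clusters,
    transforms = list(interictal_to_ictal = t_i2i, ictal_to_mri = t_i2m),
    intermediates = list(mask_spect = mask_spect, ictal_norm = ictal_n,
                         interictal_norm = inter_n, diff = diff,
                         diff_smoothed = diff_s),
    params = list(fwhm_mm = fwhm_mm, z_threshold = z_threshold,
                  min_size = min_size, norm_target = norm_target)),
    class = "siscom_result")
}

#' @export
print.siscom_result <- function(x, ...) {
  cat("<siscom_result>\n")
  print(x$clusters)
  invisible(x)
}
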