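#' Scalar 3-D image volume
#'
#' The carrier type for every image grid in the package: SPECT scans, MRI,
#' difference images, z-maps and masks. A `volume3d` couples a 3-D numeric
#' array with a 4x4 voxel-to-world affine. The world frame is RAS
#' millimetres and voxel indices are 0-based in the affine convention, i.e.
#' the world position of array element `[i+1, j+1, k+1]` is
#' `affine %*% c(i, j, k, 1)`.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix; must be
#'   invertible with strictly positive voxel sizes (column norms).
#' @return An object of class `volume3d` with fields `data` and `affine`.
#' @export
as_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop_ezloc(sprintf("volume data must be 3-D (got %d-D)",
                       length(dim(data))), "ezloc_dimensionality_error")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)))
    stop_ezloc("affine must be a 4x4 matrix", "ezloc_parameter_error")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0) || abs(det(affine)) < 1e-12)
    stop_ezloc("affine must be invertible with positive voxel sizes",
               "ezloc_parameter_error")
  structure(list(data = data, affine = affine, frame = "RAS"),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_sizes(x)
  cat(sprintf("<volume3d> %d x %d x %d voxels, %.3g x %.3g x %.3g mm (RAS)\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  invisible(x)
}

#' Voxel sizes of a volume (mm per axis)
#' @param vol A `volume3d` or `binary_mask`.
#' @return Length-3 numeric vector.
#' @export
voxel_sizes <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

#' Binary 3-D mask
#'
#' Strictly two-valued companion of [as_volume()]; used for brain masks,
#' cluster masks, EZ renderings and resection masks.
#'
#' @param data 3-D array coercible to logical (values must be 0/1/TRUE/FALSE).
#' @param affine As in [as_volume()].
#' @return An object of class `binary_mask`.
#' @export
as_mask <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop_ezloc("mask data must be 3-D", "ezloc_dimensionality_error")
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1, TRUE, FALSE)))
    stop_ezloc("mask must be two-valued (0/1)", "ezloc_parameter_error")
  v <- as_volume(array(1, dim(data)), affine)  # validates the affine
  structure(list(data = array(as.logical(data), dim(data)),
                 affine = v$affine, frame = "RAS"),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d set\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-4) {
  all(dim(a$data) == dim(b$data)) && all(abs(a$affine - b$affine) <= tol)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`). Integer voxel
#' data are preserved exactly; float data value-exact. 4-D files are
#' rejected with the offending shape. Non-finite voxels are handled per
#' `na_policy`: `"reject"` (default) raises an error reporting the count,
#' `"zero"` replaces them with 0.
#'
#' @param path File path.
#' @param na_policy `"reject"` or `"zero"`.
#' @param mask Logical: return a [as_mask()] object (data thresholded at
#'   `> 0`) instead of a volume.
#' @return A `volume3d` (or `binary_mask` when `mask = TRUE`).
#' @export
read_volume <- function(path, na_policy = c("reject", "zero"), mask = FALSE) {
  na_policy <- match.arg(na_policy)
  if (!file.exists(path))
    stop_ezloc(sprintf("file not found: %s", path), "ezloc_io_error")
  r <- read_nifti(path)
  nbad <- sum(!is.finite(r$data))
  if (nbad > 0) {
    if (na_policy == "reject")
      stop_ezloc(sprintf("volume contains %d non-finite voxel(s): %s",
                         nbad, path), "ezloc_format_error")
    r$data[!is.finite(r$data)] <- 0
  }
  if (mask) as_mask(r$data > 0, r$affine) else as_volume(r$data, r$affine)
}

#' Write a volume or mask as NIfTI-1
#'
#' @param vol A `volume3d` or `binary_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype Storage type; masks default to `uint8`, volumes to
#'   `float64` (value-exact round trips).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, datatype = NULL) {
  if (inherits(vol, "binary_mask")) {
    write_nifti(array(as.integer(vol$data), dim(vol$data)), vol$affine, path,
                datatype %||% "uint8")
  } else {
    write_nifti(vol$data, vol$affine, path, datatype %||% "float64")
  }
  invisible(path)
}

#' Zero a volume outside a binary mask
#'
#' Voxels outside the mask are set to 0; voxels inside are unchanged. Both
#' inputs must live on the identical grid (same shape, affines equal within
#' 1e-4 mm).
#'
#' @param vol A `volume3d`.
#' @param mask A `binary_mask` on the same grid.
#' @return Masked `volume3d`.
#' @export
apply_mask <- function(vol, mask) {
  if (!same_grid(vol, mask))
    stop_ezloc("volume and mask are on different grids; resample first",
               "ezloc_alignment_error")
  out <- vol
  out$data[!mask$data] <- 0
  out
}

## ---- rigid transforms -----------------------------------------------------

#' Rigid (6-DOF) spatial transform
#'
#' Parameterized by three Euler angles in degrees (applied z-y-x about a
#' center point in world mm) followed by a translation in mm. Used both as
#' the registration search space and as the misregistration model of the
#' synthetic module.
#'
#' @param rotation Length-3 angles (degrees, z-y-x order).
#' @param translation Length-3 offsets (mm).
#' @param center Length-3 rotation center (world mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rot3 <- function(deg) {
  r <- deg * pi / 180
  cz <- cos(r[1]); sz <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[3]); sx <- sin(r[3])
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rz %*% Ry %*% Rx
}

#' 4x4 world-to-world matrix of a rigid transform
#' @param tf A `rigid_transform` or a 4x4 matrix (returned unchanged).
#' @return 4x4 homogeneous matrix mapping world mm to world mm.
#' @export
transform_matrix <- function(tf) {
  if (is.matrix(tf)) {
    stopifnot(all(dim(tf) == c(4, 4)))
    return(unname(tf))
  }
  stopifnot(inherits(tf, "rigid_transform"))
  R <- rot3(tf$rotation)
  t_full <- tf$center - R %*% tf$center + tf$translation
  rbind(cbind(R, t_full), c(0, 0, 0, 1))
}

#' Invert a rigid transform (as a 4x4 matrix)
#' @param tf `rigid_transform` or 4x4 matrix.
#' @return 4x4 matrix of the inverse mapping.
#' @export
invert_transform <- function(tf) solve(transform_matrix(tf))

#' Serialize / deserialize a transform as a plain-text 4x4 matrix
#'
#' Row-major whitespace-separated text, world mm, one row per line.
#' @param tf Transform (`rigid_transform` or matrix).
#' @param path File path.
#' @return `write_transform`: the path; `read_transform`: a 4x4 matrix.
#' @export
write_transform <- function(tf, path) {
  m <- transform_matrix(tf)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.12g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(read.table(path))
  stopifnot(all(dim(m) == c(4, 4)))
  unname(m)
}

## ---- resampling -----------------------------------------------------------

# 0-based voxel index grid of a volume as a 3 x V matrix.
voxel_index_grid <- function(shape) {
  i <- seq_len(shape[1]) - 1L
  j <- seq_len(shape[2]) - 1L
  k <- seq_len(shape[3]) - 1L
  rbind(rep(i, times = shape[2] * shape[3]),
        rep(rep(j, each = shape[1]), times = shape[3]),
        rep(k, each = shape[1] * shape[2]))
}

# Trilinear sampling of `data` at continuous 0-based voxel coordinates
# (3 x V).  Points outside the grid return `fill`.
trilinear_sample <- function(data, xyz, fill = 0) {
  d <- dim(data)
  x <- xyz[1, ]; y <- xyz[2, ]; z <- xyz[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ok <- x0 >= 0 & y0 >= 0 & z0 >= 0 &
        x0 <= d[1] - 1 & y0 <= d[2] - 1 & z0 <= d[3] - 1 &
        (x0 + 1 + fx) <= d[1] & (y0 + 1 + fy) <= d[2] & (z0 + 1 + fz) <= d[3]
  # clamp corner indices into the grid; `ok` masks out-of-field points
  x1 <- pmin(pmax(x0 + 1, 0), d[1] - 1); y1 <- pmin(pmax(y0 + 1, 0), d[2] - 1)
  z1 <- pmin(pmax(z0 + 1, 0), d[3] - 1)
  x0c <- pmin(pmax(x0, 0), d[1] - 1)
  y0c <- pmin(pmax(y0, 0), d[2] - 1)
  z0c <- pmin(pmax(z0, 0), d[3] - 1)
  idx <- function(a, b, c) 1 + a + d[1] * (b + d[2] * c)
  v000 <- data[idx(x0c, y0c, z0c)]; v100 <- data[idx(x1, y0c, z0c)]
  v010 <- data[idx(x0c, y1, z0c)];  v110 <- data[idx(x1, y1, z0c)]
  v001 <- data[idx(x0c, y0c, z1)];  v101 <- data[idx(x1, y0c, z1)]
  v011 <- data[idx(x0c, y1, z1)];   v111 <- data[idx(x1, y1, z1)]
  out <- (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                     fy * ((1 - fx) * v010 + fx * v110)) +
         fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
               fy * ((1 - fx) * v011 + fx * v111))
  out[!ok] <- fill
  out
}

#' Resample a volume onto a target grid under a rigid transform
#'
#' Pull-style trilinear interpolation: each target voxel's world position
#' `x` is mapped through `transform` (target world mm to source world mm)
#' and the source volume is sampled there. Voxels mapping outside the
#' source field of view become 0.
#'
#' @param vol Source `volume3d` (or `binary_mask`, resampled as 0/1 and
#'   re-thresholded at 0.5).
#' @param target `volume3d`/`binary_mask` supplying the output grid, or a
#'   list with `shape` and `affine`.
#' @param transform `rigid_transform`, 4x4 matrix, or `NULL` for identity.
#' @return A `volume3d` (or `binary_mask`) on the target grid.
#' @export
resample_to <- function(vol, target, transform = NULL) {
  tmat <- if (is.null(transform)) diag(4) else transform_matrix(transform)
  tgt_shape <- if (!is.null(target$data)) dim(target$data) else target$shape
  tgt_aff <- target$affine
  is_mask <- inherits(vol, "binary_mask")
  src_data <- if (is_mask) array(as.numeric(vol$data), dim(vol$data)) else vol$data
  # single target-voxel -> source-voxel map
  M <- solve(vol$affine) %*% tmat %*% tgt_aff
  ijk <- voxel_index_grid(tgt_shape)
  src_idx <- M[1:3, 1:3] %*% ijk + M[1:3, 4]
  vals <- trilinear_sample(src_data, src_idx, fill = 0)
  out <- array(vals, dim = tgt_shape)
  if (is_mask) as_mask(out > 0.5, tgt_aff) else as_volume(out, tgt_aff)
}

# World coordinates (3 x V) of every voxel of a grid.
grid_world_coords <- function(vol) {
  ijk <- voxel_index_grid(dim(vol$data))
  vol$affine[1:3, 1:3] %*% ijk + vol$affine[1:3, 4]
}
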