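#' Mutual information between two volumes
#'
#' Shannon mutual information `MI = H(A) + H(B) - H(A,B)` in nats, computed
#' from the joint intensity histogram over voxels where both volumes are
#' nonzero (background-excluded overlap, as customary for emission images
#' pre-masked to the brain). Equal-width bins span each image's intensity
#' range over that overlap.
#'
#' @param a,b `volume3d` objects on the same grid (resample `b` first).
#' @param bins Histogram bin count per axis (>= 8).
#' @return Nonnegative scalar (nats).
#' @export
mutual_information <- function(a, b, bins = 64L) {
  if (!same_grid(a, b))
    stop_ezloc("volumes must share a grid; resample first",
               "ezloc_alignment_error")
  if (bins < 8L)
    stop_ezloc("bins must be >= 8", "ezloc_parameter_error")
  va <- as.vector(a$data); vb <- as.vector(b$data)
  keep <- va != 0 & vb != 0
  if (!any(keep))
    stop_ezloc("empty overlap region (no voxel nonzero in both volumes)",
               "ezloc_alignment_error")
  va <- va[keep]; vb <- vb[keep]
  mutual_information_values(va, vb, bins)
}

# MI of two paired value vectors (shared by the registration objective,
# which works on raw vectors to skip re-validation in the inner loop).
mutual_information_values <- function(va, vb, bins) {
  bin_of <- function(v) {
    r <- range(v)
    if (r[2] <= r[1]) return(rep(1L, length(v)))
    pmin(as.integer((v - r[1]) / (r[2] - r[1]) * bins) + 1L, as.integer(bins))
  }
  ia <- bin_of(va); ib <- bin_of(vb)
  joint <- tabulate(ia + as.integer(bins) * (ib - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins, bins))
  py <- colSums(matrix(p, bins, bins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  max(ent(px) + ent(py) - ent(p), 0)
}

# Block-mean downsampling by an integer factor, with the affine adjusted so
# world positions of the coarse voxel centers are preserved.
downsample_volume <- function(vol, factor) {
  if (factor <= 1L) return(vol)
  d <- dim(vol$data)
  nd <- d %/% factor
  if (any(nd < 4L)) return(NULL)
  crop <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                   seq_len(nd[3] * factor), drop = FALSE]
  a <- array(crop, c(factor, nd[1], factor, nd[2], factor, nd[3]))
  ds <- apply(a, c(2, 4, 6), mean)
  S <- diag(4)
  diag(S)[1:3] <- factor
  S[1:3, 4] <- (factor - 1) / 2
  as_volume(ds, vol$affine %*% S)
}

#' Rigid co-registration by mutual-information maximization
#'
#' Finds the 6-DOF rigid transform (Euler angles z-y-x about the fixed
#' volume's center, plus translation) that maximizes the mutual information
#' between `fixed` and `moving` resampled onto the fixed grid. The returned
#' transform maps fixed-space world coordinates into moving-space world
#' coordinates, so `resample_to(moving, fixed, transform_matrix(tf))`
#' aligns the moving volume with the fixed one.
#'
#' A multi-resolution pyramid (block-mean factors 4, 2, 1) with a
#' derivative-free Nelder-Mead simplex at each level makes the search
#' robust without histogram gradients. Deterministic for fixed inputs.
#'
#' @param moving,fixed `volume3d` objects with substantial world-space
#'   overlap.
#' @param bins Histogram bins for the MI objective.
#' @param max_iter Simplex iteration cap per pyramid level (recycled; the
#'   default spends most iterations on the cheap coarse levels and only
#'   polishes at full resolution).
#' @param tol Convergence tolerance on MI improvement.
#' @param init Optional initial `rigid_transform`.
#' @param pyramid Integer downsampling factors, coarse to fine.
#' @param presmooth_mm Gaussian FWHM applied to both images before
#'   optimization (standard for noisy emission images; sharpens the MI
#'   optimum; default 10 mm). 0 disables.
#' @return A `rigid_transform` with attributes `mi` (achieved MI) and
#'   `converged`.
#' @export
register_rigid <- function(moving, fixed, bins = 64L,
                           max_iter = c(300L, 200L, 150L),
                           tol = 1e-5, init = NULL, pyramid = c(4L, 2L, 1L),
                           presmooth_mm = 10) {
  for (v in list(moving, fixed)) {
    rng <- range(v$data)
    if (rng[2] <= rng[1])
      stop_ezloc("degenerate flat image (single intensity); cannot register",
                 "ezloc_degenerate_input_error")
  }
  if (presmooth_mm > 0) {
    # preserve the zero background (it defines the MI overlap region)
    sm <- function(v) {
      bg <- v$data == 0
      out <- smooth_gaussian(v, presmooth_mm)
      out$data[bg] <- 0
      out
    }
    moving <- sm(moving)
    fixed <- sm(fixed)
  }
  d <- dim(fixed$data)
  center <- as.numeric(fixed$affine %*% c((d - 1) / 2, 1))[1:3]
  p <- if (is.null(init)) rep(0, 6) else c(init$rotation, init$translation)

  # The MI objective only involves voxels where both images are nonzero,
  # so each evaluation samples the moving image at the fixed image's
  # nonzero voxels only (precomputed per pyramid level).
  objective_factory <- function(mov, fix) {
    keep <- which(fix$data != 0)
    va <- fix$data[keep]
    d <- dim(fix$data)
    i <- (keep - 1L) %% d[1]
    j <- ((keep - 1L) %/% d[1]) %% d[2]
    k <- (keep - 1L) %/% (d[1] * d[2])
    ijk <- rbind(i, j, k)
    Ainv <- solve(mov$affine)
    Afix <- fix$affine
    function(p) {
      tf <- rigid_transform(p[1:3], p[4:6], center)
      M <- Ainv %*% transform_matrix(tf) %*% Afix
      src_idx <- M[1:3, 1:3] %*% ijk + M[1:3, 4]
      vb <- trilinear_sample(mov$data, src_idx, fill = 0)
      ok <- vb != 0
      if (sum(ok) < 32L) return(0)
      -mutual_information_values(va[ok], vb[ok], bins)
    }
  }

  converged <- TRUE
  max_iter <- rep_len(max_iter, length(pyramid))
  for (li in seq_along(pyramid)) {
    f <- pyramid[li]
    mov <- downsample_volume(moving, f)
    fix <- downsample_volume(fixed, f)
    if (is.null(mov) || is.null(fix)) next
    obj <- objective_factory(mov, fix)
    # restart the simplex once at each level: Nelder-Mead simplices
    # collapse near narrow optima, and a restart re-inflates them
    for (rs in 1:2) {
      opt <- stats::optim(p, obj, method = "Nelder-Mead",
                          control = list(maxit = max_iter[li], reltol = tol,
                                         parscale = c(rep(1, 3), rep(1, 3))))
      p <- opt$par
    }
    if (li == length(pyramid) && opt$convergence != 0 &&
        max_iter[li] >= 200L)
      converged <- FALSE
  }
  tf <- rigid_transform(p[1:3], p[4:6], center)
  attr(tf, "mi") <- -objective_factory(moving, fixed)(p)
  attr(tf, "converged") <- converged
  if (!converged)
    warn_ezloc(sprintf(
      "registration stopped at max iterations (best MI %.4f); returning best-so-far transform",
      attr(tf, "mi")), "ezloc_convergence_warning")
  tf
}
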