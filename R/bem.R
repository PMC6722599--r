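# Optional boundary-element forward model: three nested closed triangle
# meshes (inner skull, outer skull, scalp) with piecewise-constant
# conductivity, constant-potential collocation at triangle centroids and
# analytic solid-angle integrals.  The analytic concentric-sphere model
# (leadfield_sphere3) is the package's required reference; the BEM exists
# for realistic geometry and is validated against the sphere solution on
# spherical meshes.

# Signed solid angles of all triangles of a mesh viewed from points X
# (P x 3): van Oosterom & Strackee's analytic formula.  Returns P x F.
solid_angles <- function(vertices, faces, X) {
  P <- nrow(X)
  FF <- nrow(faces)
  out <- matrix(0, P, FF)
  for (t in seq_len(FF)) {
    r1 <- sweep(-X, 2, vertices[faces[t, 1], ], "+")
    r2 <- sweep(-X, 2, vertices[faces[t, 2], ], "+")
    r3 <- sweep(-X, 2, vertices[faces[t, 3], ], "+")
    n1 <- row_norms(r1); n2 <- row_norms(r2); n3 <- row_norms(r3)
    num <- r1[, 1] * (r2[, 2] * r3[, 3] - r2[, 3] * r3[, 2]) -
           r1[, 2] * (r2[, 1] * r3[, 3] - r2[, 3] * r3[, 1]) +
           r1[, 3] * (r2[, 1] * r3[, 2] - r2[, 2] * r3[, 1])
    den <- n1 * n2 * n3 + rowSums(r1 * r2) * n3 +
           rowSums(r1 * r3) * n2 + rowSums(r2 * r3) * n1
    out[, t] <- 2 * atan2(num, den)
  }
  out
}

mesh_centroids <- function(vertices, faces) {
  (vertices[faces[, 1], ] + vertices[faces[, 2], ] +
     vertices[faces[, 3], ]) / 3
}

# Infinite-medium dipole potential (SI: positions m, sigma S/m, unit
# moment A*m along `orient`), at points X from sources at `pos`.
dipole_vinf <- function(X, pos, orient, sigma) {
  P <- nrow(X); N <- nrow(pos)
  V <- matrix(0, P, N)
  for (s in seq_len(N)) {
    d <- sweep(X, 2, pos[s, ])
    r3 <- row_norms(d)^3
    V[, s] <- (d %*% orient[s, ]) / (4 * pi * sigma * r3)
  }
  V
}

#' Three-compartment BEM leadfield
#'
#' Linear system over nested closed triangulated surfaces (inner skull,
#' outer skull, scalp; conductivities inside-out, vacuum outside) with
#' constant potential per triangle, collocation at centroids, analytic
#' solid-angle integrals and deflation of the constant-potential
#' nullspace. Electrode potentials are evaluated through the interior
#' integral representation at points pulled slightly inside the scalp,
#' then average-referenced.
#'
#' @param surfaces List of 3 meshes (each with `vertices` in mm and
#'   `faces`), ordered inner skull, outer skull, scalp; must be nested and
#'   non-intersecting.
#' @param conductivities Length-3 conductivities (S/m): brain, skull,
#'   scalp.
#' @param elec An `electrode_set` (positions on/near the scalp).
#' @param src A `source_space` with all vertices strictly inside the inner
#'   skull.
#' @return A `leadfield` with model tag `"bem3"`.
#' @export
leadfield_bem3 <- function(surfaces, conductivities, elec, src) {
  stopifnot(length(surfaces) == 3L, length(conductivities) == 3L)
  if (any(conductivities <= 0))
    stop_ezloc("conductivities must be positive", "ezloc_parameter_error")
  # nesting check by bounding radii about the joint centroid
  ctr <- colMeans(do.call(rbind, lapply(surfaces, `[[`, "vertices")))
  rmax <- vapply(surfaces, function(s)
    max(row_norms(sweep(s$vertices, 2, ctr))), 0)
  rmin <- vapply(surfaces, function(s)
    min(row_norms(sweep(s$vertices, 2, ctr))), 0)
  if (!(rmax[1] < rmin[2] && rmax[2] < rmin[3]))
    stop_ezloc("surfaces must be nested and non-intersecting (inner skull < outer skull < scalp)",
               "ezloc_geometry_error")

  sig_in <- conductivities                  # conductivity inside each surface
  sig_out <- c(conductivities[2:3], 0)      # outside each surface
  mm <- 1e-3                                # mm -> m
  cent <- lapply(surfaces, function(s)
    mesh_centroids(s$vertices, s$faces) * mm)
  nf <- vapply(surfaces, function(s) nrow(s$faces), 0L)
  ntot <- sum(nf)
  surf_of <- rep(1:3, nf)
  X <- do.call(rbind, cent)

  # assemble the solid-angle block matrix
  Omega <- matrix(0, ntot, ntot)
  col0 <- 0L
  for (j in 1:3) {
    Omega[, (col0 + 1):(col0 + nf[j])] <-
      solid_angles(surfaces[[j]]$vertices * mm, surfaces[[j]]$faces, X)
    col0 <- col0 + nf[j]
  }
  # self-surface diagonal from the closure identity (sum over the own
  # surface seen from just inside a point on it equals 2*pi)
  for (j in 1:3) {
    idx <- which(surf_of == j)
    for (ii in idx) {
      Omega[ii, ii] <- 0
      Omega[ii, ii] <- 2 * pi - sum(Omega[ii, idx])
    }
  }

  # Geselowitz surface equation (with solid angles measured from the
  # observation point toward the surface): sigma_bar V - (1/4pi) sum_j
  # (sigma_in - sigma_out) int V dOmega = sigma_s V_inf
  w <- (sig_in - sig_out)[surf_of] / (4 * pi)     # per column (source surface)
  cdiag <- (sig_in + sig_out)[surf_of] / 2        # per row (observation)
  A <- -sweep(Omega, 2, w, "*")
  diag(A) <- diag(A) + cdiag
  # deflation of the constant nullspace (insulated exterior)
  A <- A + mean(cdiag) / ntot

  src_pos <- src$vertices * mm
  if (max(row_norms(sweep(src$vertices, 2, ctr))) >= rmin[1])
    stop_ezloc("source vertices must lie strictly inside the inner skull",
               "ezloc_geometry_error")
  g <- sig_in[1] * dipole_vinf(X, src_pos, src$orientations, sig_in[1])
  kap <- rcond(A)
  if (kap < 1e-12)
    stop_ezloc(sprintf("BEM system ill-conditioned (rcond %.3g)", kap),
               "ezloc_numeric_error")
  V <- solve(A, g)                                 # ntot x N surface potentials

  # electrode potentials via the interior representation, 2% inside scalp
  epos <- sweep(elec$positions, 2, ctr)
  epos <- sweep(normalize_rows(epos) *
                  (0.98 * min(row_norms(sweep(surfaces[[3]]$vertices, 2, ctr)))),
                2, ctr, "+") * mm
  OmE <- matrix(0, nrow(epos), ntot)
  col0 <- 0L
  for (j in 1:3) {
    OmE[, (col0 + 1):(col0 + nf[j])] <-
      solid_angles(surfaces[[j]]$vertices * mm, surfaces[[j]]$faces, epos)
    col0 <- col0 + nf[j]
  }
  gE <- sig_in[1] * dipole_vinf(epos, src_pos, src$orientations, sig_in[1])
  gain <- (gE + sweep(OmE, 2, w, "*") %*% V) / sig_in[3]
  gain <- gain * 1e-9 * 1e6                        # per nA*m, in uV
  gain <- sweep(gain, 2, colMeans(gain))
  structure(list(gain = gain, model = "bem3", units = "uV per nA*m",
                 reference = "average", labels = elec$labels,
                 radii_mm = NULL, conductivities = conductivities,
                 center = ctr),
            class = "leadfield")
}

#' Relative difference measure (RDM) between leadfield columns
#'
#' `RDM = || g1/||g1|| - g2/||g2|| ||` per source column: the standard
#' shape-error metric between two forward solutions (0 = identical shape,
#' 2 = opposite).
#'
#' @param lf1,lf2 `leadfield`s (or gain matrices) with matching shapes.
#' @return Numeric vector of per-source RDM values.
#' @export
leadfield_rdm <- function(lf1, lf2) {
  g1 <- if (is.list(lf1)) lf1$gain else lf1
  g2 <- if (is.list(lf2)) lf2$gain else lf2
  stopifnot(all(dim(g1) == dim(g2)))
  n1 <- sqrt(colSums(g1^2)); n2 <- sqrt(colSums(g2^2))
  sqrt(colSums((sweep(g1, 2, n1, "/") - sweep(g2, 2, n2, "/"))^2))
}
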