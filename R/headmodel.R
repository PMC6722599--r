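# Source space, electrodes and the EEG forward model.
#
# The required, tested forward model is the analytic concentric three-shell
# sphere (brain / skull / scalp); a linear-collocation BEM over nested
# triangulated surfaces is provided as an optional tier (see bem.R).

## ---- source space ---------------------------------------------------------

base_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_mesh <- function(vertices, faces) {
  midpoint_key <- function(a, b) paste(min(a, b), max(a, b))
  cache <- new.env(parent = emptyenv())
  verts <- vertices
  get_mid <- function(a, b) {
    key <- midpoint_key(a, b)
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- (verts[a, ] + verts[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    verts <<- rbind(verts, m)
    cache[[key]] <- nrow(verts)
    nrow(verts)
  }
  newf <- matrix(0L, nrow(faces) * 4L, 3L)
  r <- 0L
  for (t in seq_len(nrow(faces))) {
    a <- faces[t, 1]; b <- faces[t, 2]; c_ <- faces[t, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
    newf[r + 1L, ] <- c(a, ab, ca)
    newf[r + 2L, ] <- c(b, bc, ab)
    newf[r + 3L, ] <- c(c_, ca, bc)
    newf[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(vertices = verts, faces = newf)
}

vertex_adjacency <- function(faces, nvert) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  adj <- vector("list", nvert)
  sp <- split(e[, 2], e[, 1])
  for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  adj
}

new_source_space <- function(vertices, faces, orientations) {
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  dimnames(orientations) <- NULL
  structure(list(vertices = vertices, faces = faces,
                 orientations = orientations,
                 adjacency = vertex_adjacency(faces, nrow(vertices))),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Icosphere cortical source space
#'
#' Icosahedral tessellation of a sphere with radial dipole orientations; the
#' desk-scale stand-in for a segmented cortical surface. Vertex count is
#' `10 * 4^subdivisions + 2`.
#'
#' @param subdivisions Subdivision level, 1..5.
#' @param radius_mm Sphere radius (mm).
#' @param center Sphere center (world mm).
#' @return A `source_space` with `vertices` (N x 3 mm), `faces`,
#'   `orientations` (unit radial normals) and vertex `adjacency`.
#' @export
make_sphere_source_space <- function(subdivisions = 3L, radius_mm = 70,
                                     center = c(0, 0, 0)) {
  if (!(subdivisions %in% 1:5))
    stop_ezloc("subdivisions must be in 1..5", "ezloc_parameter_error")
  mesh <- base_icosahedron()
  for (i in seq_len(subdivisions))
    mesh <- subdivide_mesh(mesh$vertices, mesh$faces)
  orient <- mesh$vertices  # radial, already unit
  verts <- sweep(mesh$vertices * radius_mm, 2, center, "+")
  new_source_space(verts, mesh$faces, orient)
}

# Area-weighted vertex normals; degenerate (zero-area) faces excluded.
vertex_normals <- function(vertices, faces) {
  n <- matrix(0, nrow(vertices), 3)
  ndegen <- 0L
  for (t in seq_len(nrow(faces))) {
    a <- vertices[faces[t, 1], ]; b <- vertices[faces[t, 2], ]
    c_ <- vertices[faces[t, 3], ]
    cr <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
            (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
            (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    if (sum(cr^2) < 1e-24) { ndegen <- ndegen + 1L; next }
    for (vv in faces[t, ]) n[vv, ] <- n[vv, ] + cr / 2  # cross/2 = area-weighted
  }
  if (ndegen > 0)
    warn_ezloc(sprintf("%d degenerate (zero-area) face(s) excluded from normal computation",
                       ndegen), "ezloc_mesh_warning")
  normalize_rows(n)
}

#' Load a triangulated surface (OFF or OBJ)
#'
#' Dipole orientations are computed as area-weighted vertex normals.
#' Vertices referenced by no face are pruned with a warning; degenerate
#' faces are excluded from the normal computation.
#'
#' @param path Mesh file (`.off` or `.obj`).
#' @return A `source_space`.
#' @export
load_surface <- function(path) {
  if (!file.exists(path))
    stop_ezloc(sprintf("file not found: %s", path), "ezloc_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "off") {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (toupper(trimws(lines[1])) != "OFF")
      stop_ezloc("not an OFF file (missing OFF header)", "ezloc_format_error")
    counts <- scan(text = lines[2], quiet = TRUE)
    nv <- counts[1]; nf <- counts[2]
    vert <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                        quiet = TRUE), ncol = 3, byrow = TRUE)
    face_rows <- lines[(3 + nv):(2 + nv + nf)]
    faces <- t(vapply(face_rows, function(l) {
      x <- scan(text = l, quiet = TRUE)
      if (x[1] != 3)
        stop_ezloc(sprintf("non-triangular face with %d vertices", x[1]),
                   "ezloc_format_error")
      as.integer(x[2:4] + 1L)  # OFF is 0-based
    }, integer(3)))
    dimnames(faces) <- NULL
  } else if (ext == "obj") {
    lines <- readLines(path)
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    vert <- matrix(scan(text = paste(sub("^v ", "", vl), collapse = "\n"),
                        quiet = TRUE), ncol = 3, byrow = TRUE)
    faces <- t(vapply(fl, function(l) {
      toks <- strsplit(trimws(sub("^f ", "", l)), "\\s+")[[1]]
      if (length(toks) != 3)
        stop_ezloc(sprintf("non-triangular face with %d vertices",
                           length(toks)), "ezloc_format_error")
      as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1L))
    }, integer(3)))
    dimnames(faces) <- NULL
  } else {
    stop_ezloc(sprintf("unsupported mesh format '.%s' (use OFF or OBJ)", ext),
               "ezloc_format_error")
  }
  used <- sort(unique(as.vector(faces)))
  if (length(used) < nrow(vert)) {
    warn_ezloc(sprintf("%d unreferenced vertex/vertices pruned",
                       nrow(vert) - length(used)), "ezloc_mesh_warning")
    remap <- integer(nrow(vert))
    remap[used] <- seq_along(used)
    vert <- vert[used, , drop = FALSE]
    faces <- matrix(remap[faces], ncol = 3)
  }
  new_source_space(vert, faces, vertex_normals(vert, faces))
}

#' Write a surface as OFF
#' @param src A `source_space` (or list with `vertices` and `faces`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_surface <- function(src, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(src$vertices), nrow(src$faces)), con)
  writeLines(apply(src$vertices, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(apply(src$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

## ---- electrodes -----------------------------------------------------------

# Unit-sphere directions of the 19-channel 10-20 montage (RAS: +x right,
# +y anterior, +z up).  Outer-ring electrodes sit on the equator at 36
# degree spacing; midline Fz/Pz at 36 degrees from the vertex; C3/C4 on the
# coronal arc; F3/F4/P3/P4 as great-circle midpoints of their 10-20
# neighbors, which is their defining construction.
montage_1020_unit <- function() {
  eq <- function(phi_deg) {   # azimuth from anterior midline, + toward left
    p <- phi_deg * pi / 180
    c(-sin(p), cos(p), 0)
  }
  tilt <- function(ax, deg) { # polar angle from vertex along axis ax
    a <- deg * pi / 180
    v <- c(0, 0, cos(a))
    v[ax] <- sin(a)
    v
  }
  pos <- list(
    Fp1 = eq(18), Fp2 = eq(-18), F7 = eq(54), F8 = eq(-54),
    T3 = eq(90), T4 = eq(-90), T5 = eq(126), T6 = eq(-126),
    O1 = eq(162), O2 = eq(-162),
    Fz = tilt(2, 36), Pz = { v <- tilt(2, 36); v[2] <- -v[2]; v },
    Cz = c(0, 0, 1),
    C3 = { v <- tilt(1, 36); v[1] <- -v[1]; v }, C4 = tilt(1, 36))
  mid <- function(a, b) { m <- pos[[a]] + pos[[b]]; m / sqrt(sum(m^2)) }
  pos$F3 <- mid("Fz", "F7"); pos$F4 <- mid("Fz", "F8")
  pos$P3 <- mid("Pz", "T5"); pos$P4 <- mid("Pz", "T6")
  order <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
             "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  m <- do.call(rbind, pos[order])
  rownames(m) <- order
  m
}

#' Standard EEG electrode montage on a spherical scalp
#'
#' Places a named montage on a sphere of the given scalp radius by the
#' standard angular 10-20 construction. Supported montages: `"10-20"`
#' (19 channels) and the reduced subsets `"10-20-frontal"` /
#' `"10-20-posterior"`.
#'
#' @param name Montage id.
#' @param scalp_radius_mm Scalp sphere radius (mm).
#' @param center Sphere center (world mm).
#' @return An `electrode_set`: list with `labels` and `positions` (M x 3 mm).
#' @export
standard_montage <- function(name = "10-20", scalp_radius_mm = 88,
                             center = c(0, 0, 0)) {
  full <- montage_1020_unit()
  supported <- c("10-20", "10-20-frontal", "10-20-posterior")
  if (!name %in% supported)
    stop_ezloc(sprintf("unknown montage '%s'; supported: %s", name,
                       paste(supported, collapse = ", ")),
               "ezloc_parameter_error")
  keep <- switch(name,
    "10-20" = rownames(full),
    "10-20-frontal" = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3",
                        "C3", "Cz", "C4", "T4", "T5", "P3", "Pz", "P4"),
    "10-20-posterior" = c("F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
                          "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1"))
  m <- full[keep, , drop = FALSE]
  pos <- sweep(m * scalp_radius_mm, 2, center, "+")
  structure(list(labels = rownames(m), positions = unname(pos)),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("<electrode_set> %d electrodes: %s\n", length(x$labels),
              paste(utils::head(x$labels, 8), collapse = " ")))
  invisible(x)
}

#' Read / write electrode positions as TSV (label, x, y, z in mm)
#' @param path File path.
#' @return `read_electrodes`: an `electrode_set`.
#' @export
read_electrodes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(labels = as.character(df[[1]]),
                 positions = unname(as.matrix(df[, 2:4]))),
            class = "electrode_set")
}

#' @rdname read_electrodes
#' @param elec An `electrode_set`.
#' @export
write_electrodes <- function(elec, path) {
  df <- data.frame(label = elec$labels, x_mm = elec$positions[, 1],
                   y_mm = elec$positions[, 2], z_mm = elec$positions[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- three-shell sphere forward model -------------------------------------

# Radial transfer coefficients G_n for a layered concentric sphere.
# Radii are normalized by the outermost radius.  In each layer the order-n
# potential is a r^n + b r^-(n+1); the singular (dipole) term in the
# innermost layer has unit coefficient and the outer boundary is
# insulating.  Coefficients are propagated across interfaces with the
# analytic 2x2 transfer map (continuity of potential and radial current),
# which stays well-conditioned at high order; G_n is the potential factor
# at the outer surface.
sphere_transfer_coefs <- function(nmax, rho, sigma) {
  nlay <- length(sigma)
  G <- numeric(nmax)
  for (n in seq_len(nmax)) {
    step <- function(ab, rho_i, sig_in, sig_out) {
      a <- ab[1]; b <- ab[2]
      rhs1 <- a * rho_i^n + b * rho_i^(-(n + 1))
      rhs2 <- sig_in * (a * n * rho_i^(n - 1) -
                        b * (n + 1) * rho_i^(-(n + 2)))
      b2 <- (n * rhs1 / rho_i - rhs2 / sig_out) * rho_i^(n + 2) / (2 * n + 1)
      a2 <- (rhs1 - b2 * rho_i^(-(n + 1))) * rho_i^(-n)
      c(a2, b2)
    }
    prop <- function(ab) {
      for (i in seq_len(nlay - 1L))
        ab <- step(ab, rho[i], sigma[i], sigma[i + 1L])
      ab
    }
    u <- prop(c(1, 0))   # response to the regular (a1) part
    w <- prop(c(0, 1))   # response to the unit singular (source) part
    # insulating outer boundary at rho = 1: n*a - (n+1)*b = 0
    a1 <- -(n * w[1] - (n + 1) * w[2]) / (n * u[1] - (n + 1) * u[2])
    ab_out <- a1 * u + w
    G[n] <- ab_out[1] + ab_out[2]
  }
  G
}

#' Analytic three-shell spherical leadfield
#'
#' Potential at scalp electrodes from unit dipoles at each source vertex
#' (fixed orientations from the source space), by the standard spherical-
#' harmonic series for a dipole inside concentric conducting shells
#' (brain, skull, scalp). The series is truncated once the remaining terms
#' fall below 1e-12 relative. The gain is average-referenced: each column
#' sums to zero.
#'
#' Units: microvolts per nA*m of dipole moment (radii in mm are converted
#' internally to SI).
#'
#' @param src A `source_space`; all vertices must lie strictly inside the
#'   innermost shell.
#' @param elec An `electrode_set`; positions are projected onto the scalp
#'   sphere radius.
#' @param radii_mm Increasing shell radii (brain, outer skull, scalp), mm.
#' @param conductivities Shell conductivities (S/m), same order.
#' @param center Sphere center (world mm).
#' @return A `leadfield`: list with `gain` (M x N, average-referenced),
#'   `model`, `units`, `labels`.
#' @export
leadfield_sphere3 <- function(src, elec, radii_mm = c(79, 82, 88),
                              conductivities = c(0.33, 0.0042, 0.33),
                              center = c(0, 0, 0)) {
  if (is.unsorted(radii_mm, strictly = TRUE))
    stop_ezloc("shell radii must be strictly increasing",
               "ezloc_parameter_error")
  if (any(conductivities <= 0))
    stop_ezloc("conductivities must be positive", "ezloc_parameter_error")
  R <- radii_mm[3]
  vpos <- sweep(src$vertices, 2, center)
  b_all <- row_norms(vpos)
  if (any(b_all >= radii_mm[1]))
    stop_ezloc(sprintf(
      "%d source(s) on/outside the innermost shell (max radius %.1f >= %.1f mm)",
      sum(b_all >= radii_mm[1]), max(b_all), radii_mm[1]),
      "ezloc_geometry_error")
  epos <- sweep(elec$positions, 2, center)
  epos <- normalize_rows(epos)          # unit directions on the scalp sphere
  gain <- sphere_potential_series(vpos, src$orientations, epos,
                                  radii_mm / R, conductivities, R)
  gain <- sweep(gain, 2, colMeans(gain))  # average reference
  structure(list(gain = gain, model = "sphere3",
                 units = "uV per nA*m", reference = "average",
                 labels = elec$labels,
                 radii_mm = radii_mm, conductivities = conductivities,
                 center = center),
            class = "leadfield")
}

# Series evaluation shared with tests.  vpos: N x 3 mm relative to center;
# orient: N x 3 unit; edir: M x 3 unit electrode directions; rho: radii/R;
# R outermost radius in mm.  Returns M x N in uV per nA*m.
sphere_potential_series <- function(vpos, orient, edir, rho, sigma, R_mm,
                                    tol = 1e-12, nmax = 400L) {
  N <- nrow(vpos); M <- nrow(edir)
  b <- row_norms(vpos)
  beta <- b / R_mm                        # normalized eccentricity
  nz <- b
  nz[nz == 0] <- 1
  zhat <- vpos / nz
  m_r <- rowSums(orient * zhat)           # radial moment component
  C <- edir %*% t(zhat)                   # M x N cos(gamma)
  ME <- edir %*% t(orient)                # M x N  m . e_hat
  Tang <- ME - C * matrix(m_r, M, N, byrow = TRUE)

  # adaptive series order: remaining terms scale like beta^n
  bmax <- min(max(beta), 0.995)
  if (bmax > 0)
    nmax <- min(nmax, max(40L, ceiling(log(tol / 100) / log(bmax)) + 20L))
  G <- sphere_transfer_coefs(nmax, rho, sigma)
  # Legendre recurrences over the whole M x N matrix
  P_prev <- matrix(1, M, N)   # P_0
  P_cur <- C                  # P_1
  dP_prev <- matrix(0, M, N)  # P'_0
  dP_cur <- matrix(1, M, N)   # P'_1
  V <- matrix(0, M, N)
  beta_pow <- rep(1, N)       # beta^(n-1)
  for (n in seq_len(nmax)) {
    if (n > 1) {
      P_new <- ((2 * n - 1) * C * P_cur - (n - 1) * P_prev) / n
      dP_new <- C * dP_cur + n * P_cur
      P_prev <- P_cur; P_cur <- P_new
      dP_prev <- dP_cur; dP_cur <- dP_new
      beta_pow <- beta_pow * beta
    }
    coef <- G[n] * beta_pow   # length N
    term <- P_cur * matrix(coef * n * m_r, M, N, byrow = TRUE) +
            dP_cur * Tang * matrix(coef, M, N, byrow = TRUE)
    V <- V + term
    # truncate when the worst-case remaining magnitude is negligible
    if (n >= 20 && max(abs(coef)) * max(n^2, 1) < tol * max(max(abs(V)), 1e-30))
      break
  }
  # prefactor 1/(4 pi sigma_1 R^2), SI: R in m, moment 1 nA*m -> uV
  R_m <- R_mm / 1000
  pref <- 1 / (4 * pi * sigma[1] * R_m^2)  # V per A*m
  V * pref * 1e-3                          # uV per nA*m
}

# Closed-form potential for a dipole in a homogeneous sphere with
# insulating exterior (generating-function summation of the series); the
# independent oracle for the equal-conductivity limit.
sphere_potential_homogeneous <- function(vpos, orient, edir, R_mm, sigma) {
  N <- nrow(vpos); M <- nrow(edir)
  b <- row_norms(vpos)
  stopifnot(all(b > 0))
  zhat <- vpos / b
  m_r <- rowSums(orient * zhat)
  C <- edir %*% t(zhat)
  ME <- edir %*% t(orient)
  Tang <- ME - C * matrix(m_r, M, N, byrow = TRUE)
  Tmat <- matrix(b / R_mm, M, N, byrow = TRUE)
  Delta <- sqrt(1 - 2 * Tmat * C + Tmat^2)
  rad <- 2 * Tmat * (C - Tmat) / Delta^3 + 1 / Delta - 1
  tang <- Tmat * (2 / Delta^3 + (Delta + 1) / (Delta * (1 - Tmat * C + Delta)))
  V <- rad * matrix(m_r, M, N, byrow = TRUE) + tang * Tang
  V <- V / matrix(b, M, N, byrow = TRUE) / R_mm  # 1/(b R) factor, mm^-2
  # mm^-2 -> m^-2 (1e6), V -> uV (1e6), per A*m -> per nA*m (1e-9)
  V / (4 * pi * sigma) * 1e6 * 1e6 * 1e-9
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %s, %d electrodes x %d sources, %s (%s reference)\n",
              x$model, nrow(x$gain), ncol(x$gain), x$units, x$reference))
  invisible(x)
}

#' Cache a leadfield as a portable binary matrix with JSON sidecar
#'
#' The gain matrix is stored as little-endian float64 (column-major) with a
#' JSON sidecar describing shape, model, units and montage.
#'
#' @param lf A `leadfield`.
#' @param path Output path for the binary matrix (sidecar at `<path>.json`).
#' @return The path, invisibly.
#' @export
write_leadfield <- function(lf, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(lf$gain), con, size = 8L, endian = "little")
  close(con)
  meta <- list(shape = dim(lf$gain), model = lf$model, units = lf$units,
               reference = lf$reference, labels = lf$labels,
               radii_mm = lf$radii_mm, conductivities = lf$conductivities,
               center = lf$center)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  vals <- readBin(con, "double", n = prod(meta$shape), size = 8L,
                  endian = "little")
  close(con)
  structure(list(gain = matrix(vals, meta$shape[1], meta$shape[2]),
                 model = meta$model, units = meta$units,
                 reference = meta$reference, labels = meta$labels,
                 radii_mm = meta$radii_mm,
                 conductivities = meta$conductivities,
                 center = meta$center),
            class = "leadfield")
}
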