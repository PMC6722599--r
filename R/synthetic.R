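# Ground-truth fixture generation: phantom head with implanted ictal
# hyperperfusion, simulated cortical sources and scalp EEG.  Everything is
# deterministic given the scenario seed, so every pipeline stage can be
# tested end to end without patient data.
#
# Geometry note: the default 64^3 x 2 mm grid spans 128 mm, so the phantom
# uses a geometrically scaled head (brain/skull/scalp radii 55/58/62 mm,
# cortex sphere 48 mm) rather than adult-head shell radii.  The forward
# physics is scale-consistent; only absolute distances shrink.

#' Scenario specification for synthetic ground-truth bundles
#'
#' Captures everything the generator needs: scenario geometry, blob
#' parameters, source/waveform parameters, noise levels and the seed that
#' fully determines all stochastic draws.
#'
#' Scenario geometries:
#' * `"focal"`: one hyperperfusion blob colocalized with one active
#'   cortical patch; a resection mask covers the focus. The
#'   concordant, favorable-outcome pattern.
#' * `"discordant"`: the blob sits 30 mm posterior to the active source
#'   and the resection covers neither (failed-surgery geometry, the
#'   unfavorable-outcome pattern).
#' * `"multifocal"`: two foci in different lobes (right frontal, left
#'   temporal), both perfused and electrically active; no resection.
#'
#' @param scenario `"focal"`, `"multifocal"` or `"discordant"`.
#' @param seed Integer seed; fully determines all randomness.
#' @param shape Grid dimensions (default `c(64, 64, 64)`).
#' @param voxel_mm Isotropic voxel size (default 2).
#' @param blob_radius_mm Hyperperfusion blob radius (default 8: a confined
#'   perfusion focus, smaller than the resection).
#' @param increase Relative ictal intensity increase inside the blob
#'   (default 0.20).
#' @param noise_sd Multiplicative noise SD as a fraction of the local mean
#'   (default 0.05).
#' @param psf_fwhm_mm SPECT system resolution: the perfusion baseline is
#'   blurred with this Gaussian PSF before the blob factor is applied
#'   (default 8 mm, typical post-reconstruction SPECT resolution). Sharp
#'   emission edges are unphysical and would leave edge artifacts after
#'   registration resampling.
#' @param session_sd Spatially correlated inter-session perfusion
#'   variability: each scan is modulated by an independent smooth (25 mm)
#'   multiplicative field of this relative SD (default 0.015, calibrated
#'   so the implanted blob is recovered at top-cluster Dice >= 0.6). This is the
#'   variance component that survives smoothing and sets the z-score
#'   denominator in real subtraction imaging; without it the implanted
#'   blob's suprathreshold footprint balloons far beyond the blob.
#' @param snr_db EEG signal-to-noise ratio, channel-averaged (default 15).
#' @param misregistration Optional `rigid_transform` applied to the ictal
#'   scan (default identity).
#' @param resection_radius_mm Resection sphere radius (default 18: wider
#'   than the blob, as resections exceed the perfusion focus).
#' @param source_amp_nAm Peak dipole moment of the active patch (nA*m).
#' @param srate,n_samples EEG sampling rate and epoch length.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = c("focal", "multifocal", "discordant"),
                          seed = 1L, shape = c(64L, 64L, 64L), voxel_mm = 2,
                          blob_radius_mm = 8, increase = 0.20,
                          noise_sd = 0.05, snr_db = 15,
                          misregistration = NULL, psf_fwhm_mm = 8,
                          session_sd = 0.015,
                          resection_radius_mm = 18,
                          source_amp_nAm = 10, srate = 200, n_samples = 200L) {
  scenario <- match.arg(scenario)
  if (increase < 0)
    stop_ezloc("blob intensity increase must be >= 0", "ezloc_parameter_error")
  structure(list(scenario = scenario, seed = as.integer(seed), shape = shape,
                 voxel_mm = voxel_mm, blob_radius_mm = blob_radius_mm,
                 increase = increase, noise_sd = noise_sd, snr_db = snr_db,
                 misregistration = misregistration,
                 psf_fwhm_mm = psf_fwhm_mm, session_sd = session_sd,
                 resection_radius_mm = resection_radius_mm,
                 source_amp_nAm = source_amp_nAm, srate = srate,
                 n_samples = as.integer(n_samples),
                 # scaled head geometry fitting the default grid
                 brain_radius_mm = 55, skull_radius_mm = 58,
                 scalp_radius_mm = 62, cortex_radius_mm = 48),
            class = "scenario_spec")
}

#' Phantom head: smooth-baseline brain in a head shell
#'
#' Spherical "brain" of smoothly varying baseline perfusion intensity
#' inside a larger "head" shell, with a brain mask. Deterministic given
#' the seed.
#'
#' @param shape Grid dims (each >= 32).
#' @param voxel_mm Isotropic voxel size (mm).
#' @param seed RNG seed for the smooth baseline field.
#' @param brain_radius_mm,head_radius_mm Sphere radii (mm).
#' @return List with `mri` (`volume3d`) and `brain` (`binary_mask`).
#' @export
make_phantom_head <- function(shape = c(64L, 64L, 64L), voxel_mm = 2,
                              seed = 1L, brain_radius_mm = 55,
                              head_radius_mm = 62) {
  if (any(shape < 32L))
    stop_ezloc("phantom grid must be at least 32^3", "ezloc_parameter_error")
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- -voxel_mm * (shape - 1) / 2   # world origin at the center
  vol0 <- as_volume(array(0, shape), aff)
  w <- grid_world_coords(vol0)
  r <- sqrt(colSums(w^2))
  brain <- array(r <= brain_radius_mm, shape)
  head <- array(r <= head_radius_mm, shape)
  # smooth multiplicative baseline field: white noise smoothed at 15 mm
  field <- with_seed(seed, array(stats::rnorm(prod(shape)), shape))
  field <- smooth_gaussian(as_volume(field, aff), fwhm_mm = 15)$data
  field <- field / max(stats::sd(field), 1e-12)
  mri <- array(0, shape)
  mri[head] <- 25
  mri[brain] <- 90 * (1 + 0.10 * field[brain])
  # anatomical structure (makes rotations identifiable and the baseline
  # realistic): ventricle-like low-uptake ellipsoids, a posterior-inferior
  # cerebellum-like region, and asymmetric left/right uptake
  ellipsoid <- function(center, semi) {
    dx <- sweep(w, 1, center)
    array(colSums((dx / semi)^2) <= 1, shape)
  }
  vent_l <- ellipsoid(c(-11, 8, 6), c(7, 16, 9))
  vent_r <- ellipsoid(c(11, 12, 6), c(6, 12, 8))
  cereb <- ellipsoid(c(0, -30, -24), c(24, 16, 12))
  mri[vent_l & brain] <- mri[vent_l & brain] * 0.35
  mri[vent_r & brain] <- mri[vent_r & brain] * 0.35
  mri[cereb & brain] <- mri[cereb & brain] * 1.25
  lat <- 1 + 0.05 * w[1, ] / max(abs(w[1, ]))
  mri[brain] <- mri[brain] * array(lat, shape)[brain]
  mri[brain] <- pmax(mri[brain], 10)
  list(mri = as_volume(mri, aff), brain = as_mask(brain, aff))
}

# Spherical blob indicator around world-mm centers.
blob_indicator <- function(vol, centers, radius_mm) {
  w <- grid_world_coords(vol)
  ind <- rep(FALSE, ncol(w))
  centers <- if (is.matrix(centers)) centers else matrix(centers, nrow = 1)
  for (i in seq_len(nrow(centers)))
    ind <- ind | (colSums((w - centers[i, ])^2) <= radius_mm^2)
  array(ind, dim(vol$data))
}

#' Synthetic ictal/interictal SPECT pair with implanted hyperperfusion
#'
#' `interictal = baseline * (1 + noise)`;
#' `ictal = baseline * (1 + increase * blob) * (1 + noise)`, optionally
#' resampled through the misregistration transform. Noise is Gaussian with
#' SD proportional to the local mean (post-reconstruction Poisson proxy).
#'
#' @param head Output of [make_phantom_head()].
#' @param spec A `scenario_spec`; `blob_centers` (matrix of world mm) may
#'   be passed explicitly to override the scenario geometry.
#' @param blob_centers Optional world-mm centers (rows).
#' @return List with `ictal`, `interictal` (`volume3d`) and `blob`
#'   (`binary_mask`, true hyperperfusion region in MRI space).
#' @export
make_spect_pair <- function(head, spec, blob_centers = NULL) {
  baseline <- head$mri$data * 0
  baseline[head$brain$data] <- head$mri$data[head$brain$data]
  aff <- head$mri$affine
  psf <- spec$psf_fwhm_mm %||% 0
  if (psf > 0) {
    # emission-image system resolution; applied to the baseline only, so
    # the implanted ictal/interictal ratio stays exactly 1 + increase
    baseline <- smooth_gaussian(as_volume(baseline, aff), psf)$data
    baseline[!head$brain$data] <- 0
  }
  centers <- blob_centers %||% scenario_foci(spec)$blob_centers
  centers <- if (is.matrix(centers)) centers else matrix(centers, nrow = 1)
  blob <- blob_indicator(head$mri, centers, spec$blob_radius_mm)
  if (spec$increase > 0 && any(blob & !head$brain$data))
    stop_ezloc("hyperperfusion blob extends outside the brain",
               "ezloc_geometry_error")
  shape <- dim(baseline)
  noise <- with_seed(spec$seed + 101L, list(
    a = array(stats::rnorm(prod(shape)), shape),
    b = array(stats::rnorm(prod(shape)), shape),
    fa = array(stats::rnorm(prod(shape)), shape),
    fb = array(stats::rnorm(prod(shape)), shape)))
  session_sd <- spec$session_sd %||% 0
  field <- function(x) {
    if (session_sd <= 0) return(1)
    f <- smooth_gaussian(as_volume(x, aff), 25)$data
    1 + session_sd * f / stats::sd(f[head$brain$data])
  }
  interictal <- baseline * field(noise$fa) * (1 + spec$noise_sd * noise$a)
  ictal <- baseline * field(noise$fb) * (1 + spec$increase * blob) *
    (1 + spec$noise_sd * noise$b)
  interictal[interictal < 0] <- 0
  ictal[ictal < 0] <- 0
  ictal_v <- as_volume(ictal, aff)
  if (!is.null(spec$misregistration))
    ictal_v <- resample_to(ictal_v, ictal_v, spec$misregistration)
  list(ictal = ictal_v, interictal = as_volume(interictal, aff),
       blob = as_mask(blob, aff))
}

# Scenario focus geometry: blob centers, active-source positions and the
# resection center, all in world mm.  Sources sit on the cortex sphere;
# blobs are implanted 3 mm deeper so a blob ball stays inside the brain.
scenario_foci <- function(spec) {
  rc <- spec$cortex_radius_mm
  rb <- rc - 3                     # blob-center eccentricity
  unit <- function(v) v / sqrt(sum(v^2))
  # geodesic offset: walk `dist_mm` along the sphere from direction d
  # toward world direction w
  geo <- function(d, w, dist_mm, radius) {
    t_ <- w - sum(w * d) * d
    t_ <- unit(t_)
    th <- dist_mm / radius
    unit(cos(th) * d + sin(th) * t_) * radius
  }
  src_dirs <- switch(spec$scenario,
    focal = list(unit(c(0.9, 0.35, 0.35))),           # right temporal-ish
    discordant = list(unit(c(0.6, 0.7, 0.4))),        # right frontal
    # multifocal foci sit on prior-library patch centers (the same
    # convention as the focal recovery examples), keeping the two foci
    # equally representable by the inverse model
    multifocal = list(unit(c(0.516122, 0.783452, 0.346153)),  # right frontal
                      unit(c(-1, 0, 0))))                     # left temporal
  src_pos <- lapply(src_dirs, function(d) d * rc)
  blob_centers <- switch(spec$scenario,
    focal = ,
    multifocal = do.call(rbind, lapply(src_dirs, function(d) d * rb)),
    discordant = matrix(geo(src_dirs[[1]], c(0, -1, 0), 30, rb), nrow = 1))
  resection_center <- switch(spec$scenario,
    focal = src_pos[[1]],
    discordant = geo(src_dirs[[1]], c(0, 1, 0), 30, rc),  # anterior miss
    multifocal = NULL)
  list(src_dirs = src_dirs, src_pos = src_pos, blob_centers = blob_centers,
       resection_center = resection_center)
}

#' Simulate scalp EEG from active cortical patches
#'
#' Builds true source currents as diffusion-kernel spatial profiles times a
#' damped-oscillation waveform (successive patches are delayed by a quarter
#' period), projects them through the leadfield, and adds white sensor
#' noise scaled to the requested channel-averaged SNR
#' (`10*log10(signal power / noise power) = snr_db`). `snr_db = Inf`
#' disables noise.
#'
#' @param src `source_space`.
#' @param lf `leadfield` for the matching electrode set.
#' @param active Integer vector of active vertices, or a list of vectors
#'   (one per patch).
#' @param waveform Numeric vector of length T (the source time course), or
#'   `NULL` for the default damped 6-Hz oscillation.
#' @param snr_db Channel-averaged SNR in dB.
#' @param seed RNG seed for the noise draw.
#' @param srate Sampling rate (Hz), used for the default waveform.
#' @param n_samples Epoch length for the default waveform.
#' @param amp_nAm Peak dipole moment (nA*m).
#' @param smoothness Diffusion steps of the spatial profile.
#' @return List with `eeg` (`eeg_epoch`), `J_true` (N x T nA*m),
#'   `noise_sd` (realized sensor noise SD).
#' @export
simulate_eeg <- function(src, lf, active, waveform = NULL, snr_db = 15,
                         seed = 1L, srate = 200, n_samples = 200L,
                         amp_nAm = 10, smoothness = 3L) {
  patches <- if (is.list(active)) active else list(active)
  if (!length(patches) || !length(unlist(patches)))
    stop_ezloc("active vertex set is empty", "ezloc_parameter_error")
  N <- nrow(src$vertices)
  if (any(unlist(patches) < 1L | unlist(patches) > N))
    stop_ezloc("active vertices outside the source space",
               "ezloc_parameter_error")
  if (is.null(waveform)) {
    t_s <- (0:(n_samples - 1)) / srate
    waveform <- sin(2 * pi * 6 * t_s) * exp(-t_s / 0.4)
  }
  T_ <- length(waveform)
  J <- matrix(0, N, T_)
  per <- max(1L, round(srate / 6 / 4))   # quarter period in samples
  ref_rms <- NULL
  for (p in seq_along(patches)) {
    prof <- diffusion_profile(src, patches[[p]], smoothness)
    sh <- (p - 1L) * per
    # circular shift keeps per-patch waveform energy identical
    wv <- if (sh > 0) waveform[((seq_len(T_) - 1L - sh) %% T_) + 1L]
          else waveform
    # comparably visible foci: later patches are scaled so each focus
    # contributes the same scalp signal power as the first (amp_nAm is the
    # peak moment of the first patch)
    rms <- sqrt(mean((lf$gain %*% prof)^2))
    if (is.null(ref_rms)) ref_rms <- rms
    J <- J + outer(prof * amp_nAm * (ref_rms / rms), wv)
  }
  S <- lf$gain %*% J
  if (is.finite(snr_db)) {
    sigma <- sqrt(mean(S^2) / 10^(snr_db / 10))
    noise <- with_seed(seed + 202L,
                       matrix(stats::rnorm(length(S), 0, sigma), nrow(S)))
    Y <- S + noise
  } else {
    sigma <- 0
    Y <- S
  }
  list(eeg = eeg_epoch(Y, srate, lf$labels), J_true = J, noise_sd = sigma)
}

#' Build a complete ground-truth bundle (optionally on disk)
#'
#' Generates every input the localization methodology needs — phantom MRI,
#' SPECT pair, brain/blob masks, cortical source space, electrodes,
#' leadfield, ictal EEG with true currents, and (focal/discordant
#' scenarios) a resection mask — plus a JSON manifest with the seed, the
#' scenario parameters and md5 checksums of all written files.
#'
#' @param spec A `scenario_spec`.
#' @param out_dir Output directory, or `NULL` to keep the bundle in memory
#'   only.
#' @return A `ground_truth_bundle` (list of all components; `paths` and
#'   `manifest` added when written to disk).
#' @export
make_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  head <- make_phantom_head(spec$shape, spec$voxel_mm, seed = spec$seed,
                            brain_radius_mm = spec$brain_radius_mm,
                            head_radius_mm = spec$scalp_radius_mm)
  foci <- scenario_foci(spec)
  pair <- make_spect_pair(head, spec)

  src <- make_sphere_source_space(3L, radius_mm = spec$cortex_radius_mm)
  elec <- standard_montage("10-20", spec$scalp_radius_mm)
  lf <- leadfield_sphere3(
    src, elec,
    radii_mm = c(spec$brain_radius_mm, spec$skull_radius_mm,
                 spec$scalp_radius_mm),
    conductivities = c(0.33, 0.0042, 0.33))

  active <- lapply(foci$src_pos, function(p) {
    which.min(colSums((t(src$vertices) - p)^2))
  })
  sim <- simulate_eeg(src, lf, active, snr_db = spec$snr_db,
                      seed = spec$seed, srate = spec$srate,
                      n_samples = spec$n_samples,
                      amp_nAm = spec$source_amp_nAm)

  resection <- NULL
  if (!is.null(foci$resection_center)) {
    rb <- blob_indicator(head$mri, foci$resection_center,
                         spec$resection_radius_mm)
    resection <- as_mask(rb & head$brain$data, head$mri$affine)
  }

  bundle <- structure(list(
    spec = spec, mri = head$mri, brain_mask = head$brain,
    ictal = pair$ictal, interictal = pair$interictal, blob_mask = pair$blob,
    source_space = src, electrodes = elec, leadfield = lf,
    eeg = sim$eeg, J_true = sim$J_true, active_vertices = active,
    resection = resection,
    truth = list(blob_centers = foci$blob_centers,
                 src_pos = foci$src_pos,
                 resection_center = foci$resection_center)),
    class = "ground_truth_bundle")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop_ezloc(sprintf("cannot create output directory %s", out_dir),
                 "ezloc_io_error")
    p <- function(f) file.path(out_dir, f)
    paths <- c(mri = p("mri.nii.gz"), brain_mask = p("brain_mask.nii.gz"),
               ictal = p("ictal.nii.gz"), interictal = p("interictal.nii.gz"),
               blob_mask = p("blob_mask.nii.gz"), cortex = p("cortex.off"),
               electrodes = p("electrodes.tsv"), eeg = p("eeg.tsv"),
               leadfield = p("leadfield.bin"))
    write_volume(bundle$mri, paths["mri"])
    write_volume(bundle$brain_mask, paths["brain_mask"])
    write_volume(bundle$ictal, paths["ictal"])
    write_volume(bundle$interictal, paths["interictal"])
    write_volume(bundle$blob_mask, paths["blob_mask"])
    write_surface(src, paths["cortex"])
    write_electrodes(elec, paths["electrodes"])
    write_eeg_tsv(bundle$eeg, paths["eeg"])
    write_leadfield(lf, paths["leadfield"])
    if (!is.null(resection)) {
      paths <- c(paths, resection = p("resection.nii.gz"))
      write_volume(resection, paths["resection"])
    }
    manifest <- list(
      seed = spec$seed, scenario = spec$scenario,
      params = spec[setdiff(names(spec), "misregistration")],
      misregistration = if (is.null(spec$misregistration)) NULL
                        else transform_matrix(spec$misregistration),
      files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      names(paths))))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    bundle$paths <- paths
    bundle$manifest <- manifest
  }
  bundle
}

#' @export
print.ground_truth_bundle <- function(x, ...) {
  cat(sprintf("<ground_truth_bundle> scenario=%s seed=%d, grid %s\n",
              x$spec$scenario, x$spec$seed,
              paste(dim(x$mri$data), collapse = "x")))
  invisible(x)
}
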