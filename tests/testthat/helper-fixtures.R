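# Shared fixtures, memoized so expensive objects (source space, leadfield,
# patch library) are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(build)
  .fixture_cache[[name]]
}

std_affine <- function(voxel_mm = 2, shape = c(16L, 16L, 16L)) {
  a <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  a[1:3, 4] <- -voxel_mm * (shape - 1) / 2
  a
}

rand_volume <- function(shape = c(8L, 8L, 8L), seed = 1L, voxel_mm = 2) {
  set.seed(seed)
  as_volume(array(stats::rnorm(prod(shape)), shape),
            std_affine(voxel_mm, shape))
}

rand_mask <- function(shape = c(8L, 8L, 8L), seed = 1L, p = 0.5,
                      voxel_mm = 2) {
  set.seed(seed)
  as_mask(array(stats::runif(prod(shape)) < p, shape),
          std_affine(voxel_mm, shape))
}

# Desk-scale head model shared across ESI tests: 642-vertex cortex sphere,
# 19-channel montage, three-shell leadfield, 256-patch library.
esi_fixture <- function() {
  fixture("esi", {
    src <- make_sphere_source_space(3L, radius_mm = 60)
    elec <- standard_montage("10-20", 88)
    lf <- leadfield_sphere3(src, elec, radii_mm = c(79, 82, 88),
                            conductivities = c(0.33, 0.0042, 0.33))
    lib <- build_patch_library(src, 256L, smoothness = 3L, seed = 1L)
    list(src = src, elec = elec, lf = lf, lib = lib)
  })
}

# Simulated focal epoch on the shared head model.
sim_focal_epoch <- function(center, snr_db = 20, seed = 1L, amp = 10) {
  fx <- esi_fixture()
  simulate_eeg(fx$src, fx$lf, center, snr_db = snr_db, seed = seed,
               amp_nAm = amp)
}
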