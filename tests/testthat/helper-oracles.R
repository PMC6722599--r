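# Independent brute-force oracles.  These deliberately share no code with
# the implementation paths they check.

# Connected components of a logical array under 26-connectivity by
# fixpoint dilation with explicit array shifts.
oracle_label_components <- function(bin) {
  d <- dim(bin)
  shift_or <- function(m) {
    out <- array(FALSE, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      xs <- intersect(seq_len(d[1]), seq_len(d[1]) - dx)
      ys <- intersect(seq_len(d[2]), seq_len(d[2]) - dy)
      zs <- intersect(seq_len(d[3]), seq_len(d[3]) - dz)
      out[xs + dx, ys + dy, zs + dz] <-
        out[xs + dx, ys + dy, zs + dz] | m[xs, ys, zs]
    }
    out
  }
  lab <- array(0L, d)
  cur <- 0L
  repeat {
    seed_idx <- which(bin & lab == 0L)
    if (!length(seed_idx)) break
    cur <- cur + 1L
    region <- array(FALSE, d)
    region[seed_idx[1]] <- TRUE
    repeat {
      grown <- shift_or(region) & bin
      if (identical(grown, region)) break
      region <- grown
    }
    lab[region] <- cur
  }
  lab
}

# Voxel-by-voxel confusion counting.
oracle_confusion <- function(ez, res, reg) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(reg)) {
    if (!reg[i]) next
    if (ez[i] && res[i]) tp <- tp + 1L
    else if (ez[i]) fp <- fp + 1L
    else if (res[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Two-pass mean/population-SD z-scores over a mask.
oracle_zscores <- function(diff, mask) {
  vals <- diff[mask]
  mu <- sum(vals) / length(vals)
  sd_p <- sqrt(sum((vals - mu)^2) / length(vals))
  z <- array(0, dim(diff))
  z[mask] <- (vals - mu) / sd_p
  z
}

# FWHM of a smoothed unit impulse by fitting a 1-D Gaussian profile.
oracle_impulse_fwhm <- function(profile, spacing_mm) {
  x <- (seq_along(profile) - which.max(profile)) * spacing_mm
  keep <- profile > max(profile) * 1e-6
  fit <- stats::lm(log(profile[keep]) ~ I(x[keep]^2))
  sigma <- sqrt(-1 / (2 * stats::coef(fit)[2]))
  sigma * 2 * sqrt(2 * log(2))
}

# 26-connectivity binary dilation (for monotonicity checks).
oracle_dilate <- function(bin) {
  d <- dim(bin)
  out <- array(FALSE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- intersect(seq_len(d[1]), seq_len(d[1]) - dx)
    ys <- intersect(seq_len(d[2]), seq_len(d[2]) - dy)
    zs <- intersect(seq_len(d[3]), seq_len(d[3]) - dz)
    out[xs + dx, ys + dy, zs + dz] <-
      out[xs + dx, ys + dy, zs + dz] | bin[xs, ys, zs]
  }
  out
}
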