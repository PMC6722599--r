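# The full localization methodology: three EZ hypotheses (SISCOM clusters,
# ictal ESI, ictal ESI with the SISCOM prior) plus the coincidence table
# against a resection mask when one is available.

#' Default per-stage run configuration
#'
#' Parameter blocks mirror the module defaults; unknown keys are rejected
#' so a typo cannot silently fall back to a default. Every parameter is
#' echoed into the run manifest.
#'
#' @param ... Named overrides, either top-level blocks (`siscom = list(...)`)
#'   or flattened `block.key` names.
#' @return A `run_config` list with blocks `siscom`, `esi`, `coincidence`,
#'   and `seed`.
#' @export
run_config <- function(...) {
  cfg <- list(
    siscom = list(fwhm_mm = 12, z_threshold = 2, min_size = 10L,
                  norm_target = 100, peak_z = 4),
    esi = list(n_patches = 256L, smoothness = 3L, patch_seed = 1L,
               max_iter = 128L, tol = 1e-6, frac = 0.5,
               render_radius_mm = 15, max_dist_mm = 10),
    coincidence = list(region = "brain"),
    seed = 1L)
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("seed")) { cfg[[nm]] <- ov[[nm]]; next }
    if (!nm %in% names(cfg))
      stop_ezloc(sprintf("unknown config block '%s'", nm),
                 "ezloc_parameter_error")
    for (k in names(ov[[nm]])) {
      if (!k %in% names(cfg[[nm]]))
        stop_ezloc(sprintf("unknown config key '%s.%s'", nm, k),
                   "ezloc_parameter_error")
      cfg[[nm]][[k]] <- ov[[nm]][[k]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the three-way EZ localization methodology
#'
#' Executes, on one subject bundle: (i) SISCOM, giving the hyperperfusion
#' cluster mask; (ii) ictal EEG source imaging with mathematical patch
#' priors only; (iii) ictal ESI with the SISCOM clusters injected as
#' additional spatial priors. All three EZ hypotheses are rendered on the
#' MRI grid, and — when a resection mask is supplied — compared against it
#' voxelwise (sensitivity/specificity over the brain region).
#'
#' @param bundle A `ground_truth_bundle` (or any list with the same named
#'   components: `mri`, `brain_mask`, `ictal`, `interictal`,
#'   `source_space`, `leadfield`, `eeg`, optional `resection`).
#' @param config A [run_config()].
#' @param known_transforms Optional list (`interictal_to_ictal`,
#'   `ictal_to_mri`) to skip registration.
#' @return An `ez_methodology_result` with `siscom` (full SISCOM result),
#'   `ez_siscom`/`ez_esi`/`ez_combined` (`binary_mask`s), `esi`/`combined`
#'   (`msp_result`s), and `coincidence` (data frame, or `NULL` with a
#'   notice when no resection mask is present).
#' @export
run_methodology <- function(bundle, config = run_config(),
                            known_transforms = NULL) {
  cs <- config$siscom
  sis <- run_siscom(bundle$ictal, bundle$interictal, bundle$mri,
                    bundle$brain_mask, fwhm_mm = cs$fwhm_mm,
                    z_threshold = cs$z_threshold, min_size = cs$min_size,
                    norm_target = cs$norm_target,
                    transforms = known_transforms)
  # the SISCOM EZ hypothesis: clusters peaking at or above the focus
  # criterion (extent still defined by the cluster-forming threshold)
  foci <- filter_clusters(sis$clusters, cs$peak_z)
  ez_siscom <- cluster_mask(foci)

  ce <- config$esi
  lib <- build_patch_library(bundle$source_space, ce$n_patches,
                             ce$smoothness, seed = ce$patch_seed)
  res_esi <- invert_msp(bundle$eeg, bundle$leadfield, lib,
                        max_iter = ce$max_iter, tol = ce$tol)
  ez_esi <- source_to_ez_map(res_esi, bundle$source_space, bundle$mri,
                             frac = ce$frac,
                             render_radius_mm = ce$render_radius_mm)

  sprior <- siscom_prior_components(foci, bundle$source_space,
                                    mri_to_head = NULL,
                                    max_dist_mm = ce$max_dist_mm,
                                    smoothness = ce$smoothness)
  res_comb <- invert_with_siscom_prior(bundle$eeg, bundle$leadfield, lib,
                                       sprior, max_iter = ce$max_iter,
                                       tol = ce$tol)
  ez_comb <- source_to_ez_map(res_comb, bundle$source_space, bundle$mri,
                              frac = ce$frac,
                              render_radius_mm = ce$render_radius_mm)

  coincidence <- NULL
  if (!is.null(bundle$resection)) {
    region <- bundle$brain_mask
    rows <- lapply(list(SISCOM = ez_siscom, `ictal ESI` = ez_esi$mask,
                        `ictal ESI + SISCOM` = ez_comb$mask),
                   function(m) {
                     cc <- confusion_counts(m, bundle$resection, region)
                     data.frame(sensitivity = sensitivity(cc),
                                specificity = specificity(cc),
                                tp = cc$tp, fp = cc$fp, fn = cc$fn,
                                tn = cc$tn)
                   })
    coincidence <- do.call(rbind, rows)
    coincidence <- cbind(method = rownames(coincidence), coincidence)
    rownames(coincidence) <- NULL
  } else {
    message("no resection mask supplied; coincidence analysis skipped")
  }

  structure(list(siscom = sis, foci = foci, ez_siscom = ez_siscom,
                 esi = res_esi, ez_esi = ez_esi,
                 combined = res_comb, ez_combined = ez_comb,
                 siscom_priors = sprior,
                 coincidence = coincidence, config = config),
            class = "ez_methodology_result")
}

#' @export
print.ez_methodology_result <- function(x, ...) {
  cat("<ez_methodology_result>\n")
  cat(sprintf("  SISCOM EZ: %d voxels in %d focus/foci (%d suprathreshold cluster(s))\n",
              sum(x$ez_siscom$data), length(x$foci$clusters),
              length(x$siscom$clusters$clusters)))
  cat(sprintf("  ictal ESI EZ: %d voxels\n", sum(x$ez_esi$mask$data)))
  cat(sprintf("  ictal ESI + SISCOM EZ: %d voxels\n",
              sum(x$ez_combined$mask$data)))
  if (!is.null(x$coincidence)) {
    cat("  coincidence vs resection:\n")
    cc <- x$coincidence
    for (i in seq_len(nrow(cc)))
      cat(sprintf("    %-20s sens %5.1f%%  spec %5.1f%%\n",
                  cc$method[i], cc$sensitivity[i], cc$specificity[i]))
  }
  invisible(x)
}
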