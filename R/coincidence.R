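# Coincidence analysis: voxelwise confusion counts of an estimated EZ
# against the surgical resection mask, summarized as sensitivity and
# specificity, plus optional atlas labeling of the estimate.

#' Voxelwise confusion counts within an evaluation region
#'
#' Within `region`: `tp = |ez & resection|`, `fp = |ez & !resection|`,
#' `fn = |resection & !ez|`, `tn = |region - (ez | resection)|`. The four
#' counts always sum to the region size.
#'
#' @param ez Estimated-EZ `binary_mask`.
#' @param resection Resection `binary_mask` (the gold standard).
#' @param region Evaluation-region `binary_mask` (default whole brain in
#'   the callers); must be nonempty and on the same grid.
#' @return A `coincidence_result` with counts; feed to [sensitivity()] /
#'   [specificity()].
#' @export
confusion_counts <- function(ez, resection, region) {
  if (!same_grid(ez, resection) || !same_grid(ez, region))
    stop_ezloc("ez/resection/region masks are on different grids",
               "ezloc_alignment_error")
  if (!any(region$data))
    stop_ezloc("evaluation region is empty", "ezloc_parameter_error")
  e <- ez$data & region$data
  r <- resection$data & region$data
  tp <- sum(e & r)
  fp <- sum(e & !r)
  fn <- sum(r & !e)
  tn <- sum(region$data) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 region_voxels = sum(region$data), domain = "supplied region"),
            class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat(sprintf("<coincidence_result> tp=%d fp=%d fn=%d tn=%d (%s)\n",
              x$tp, x$fp, x$fn, x$tn, x$domain))
  sens <- tryCatch(sensitivity(x), error = function(e) NA_real_)
  spec <- tryCatch(specificity(x), error = function(e) NA_real_)
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n", sens, spec))
  invisible(x)
}

#' Sensitivity (percent)
#'
#' `100 * tp / (tp + fn)`: the fraction of the resection captured by the
#' estimate. Low sensitivity means many false negatives.
#'
#' @param counts A `coincidence_result` (or list with `tp`, `fn`).
#' @return Percentage in [0, 100].
#' @export
sensitivity <- function(counts) {
  if ((counts$tp + counts$fn) <= 0)
    stop_ezloc("sensitivity undefined: empty resection (tp + fn = 0)",
               "ezloc_undefined_metric_error")
  100 * counts$tp / (counts$tp + counts$fn)
}

#' Specificity (percent)
#'
#' `100 * tn / (tn + fp)`: the method's capacity to avoid false positives
#' within the evaluation region.
#'
#' @param counts A `coincidence_result` (or list with `tn`, `fp`).
#' @return Percentage in [0, 100].
#' @export
specificity <- function(counts) {
  if ((counts$tn + counts$fp) <= 0)
    stop_ezloc("specificity undefined: degenerate region (tn + fp = 0)",
               "ezloc_undefined_metric_error")
  100 * counts$tn / (counts$tn + counts$fp)
}

#' Anatomical labeling of an EZ estimate against an integer atlas
#'
#' Tallies the overlap of the estimate with each atlas label, reporting a
#' descending-overlap list. Labels missing from the lookup are reported as
#' `label:<int>`. Background (label 0) is excluded, so fractions sum to
#' at most 1.
#'
#' @param ez `binary_mask`.
#' @param atlas `volume3d` of integer labels on the same grid.
#' @param lookup Optional data.frame/list mapping `label` to `name` (a
#'   two-column data frame or named character vector keyed by label).
#' @return data.frame with `name`, `label`, `voxels`, `fraction` (of the
#'   ez volume), sorted by descending overlap.
#' @export
label_regions <- function(ez, atlas, lookup = NULL) {
  if (!same_grid(ez, atlas))
    stop_ezloc("ez and atlas are on different grids", "ezloc_alignment_error")
  labs <- as.integer(round(atlas$data[ez$data]))
  labs <- labs[labs != 0L]
  n_ez <- sum(ez$data)
  if (!length(labs))
    return(data.frame(name = character(0), label = integer(0),
                      voxels = integer(0), fraction = numeric(0)))
  tab <- sort(table(labs), decreasing = TRUE)
  lab_ids <- as.integer(names(tab))
  name_of <- function(id) {
    nm <- NULL
    if (is.data.frame(lookup)) {
      hit <- match(id, lookup[[1]])
      if (!is.na(hit)) nm <- as.character(lookup[[2]][hit])
    } else if (!is.null(lookup)) {
      nm <- unname(lookup[as.character(id)])
      if (is.na(nm)) nm <- NULL
    }
    nm %||% sprintf("label:%d", id)
  }
  data.frame(name = vapply(lab_ids, name_of, ""),
             label = lab_ids,
             voxels = as.integer(tab),
             fraction = as.numeric(tab) / n_ez)
}
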