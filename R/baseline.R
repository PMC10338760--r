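#' Threshold-based baseline cavity segmenter
#'
#' A deterministic, non-learned stand-in for a trained segmentation model
#' so the full pipeline runs at desk scale: voxels whose HU falls inside
#' `hu_band` within the search region are selected, closed with a 1-voxel
#' morphological closing, and the largest 26-connected component is kept
#' if its physical volume reaches `min_component_mm3` (otherwise the
#' prediction is empty).  The HU band must be chosen by the user; it is a
#' test vehicle, not a clinical claim.
#'
#' @param volume `scalar_volume`.
#' @param search_region non-empty `structure_mask` restricting the search
#'   (e.g. the posterior fossa).
#' @param hu_band numeric `(low, high)`, low < high.
#' @param min_component_mm3 minimum component volume retained, mm^3.
#' @return A `structure_mask` labelled `"prediction"` (possibly empty).
#' @export
baseline_segment <- function(volume, search_region, hu_band,
                             min_component_mm3 = 100) {
  if (mask_is_empty(search_region)) stop("search region is empty")
  if (length(hu_band) != 2 || hu_band[1] >= hu_band[2])
    stop("invalid HU band: need low < high")
  check_same_grid(volume, search_region)
  dm <- dim(volume$voxels)
  sel <- search_region$voxels & volume$voxels >= hu_band[1] &
    volume$voxels <= hu_band[2]
  if (any(sel)) {
    # 1-voxel closing: Euclidean dilation then erosion in voxel units
    unit <- c(1, 1, 1)
    dil <- cpp_edt_sq(as.logical(sel), dm, unit) <= 1
    sel <- array(cpp_edt_sq(!dil, dm, unit) > 1, dim = dm)
    lab <- cpp_label_components(as.logical(sel), dm, 26L)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      big <- which.max(sizes)
      keep <- sizes[big] * prod(volume$spacing) >= min_component_mm3
      sel <- array(lab == big & keep, dim = dm)
    }
  }
  structure_mask(array(sel, dim = dm), volume, label = "prediction")
}

#' Baseline segmenter contract
#'
#' Wraps [baseline_segment()] in the pluggable segmenter contract used by
#' [run_experiment()]: `fit(training_cases)` returns a predict function
#' mapping a loaded case to a `structure_mask` on the case's grid.  The
#' baseline has no trainable parameters, so `fit` ignores the training
#' cases; the contract still records which cases each model arm was bound
#' to.
#'
#' @param hu_band HU band passed to [baseline_segment()].
#' @param min_component_mm3 minimum retained component volume, mm^3.
#' @param region name of the case mask used as search region (default
#'   `"posterior_fossa"`).
#' @return Object of class `segmenter`: list with `name` and
#'   `fit(training_cases)`.
#' @export
baseline_segmenter <- function(hu_band, min_component_mm3 = 100,
                               region = "posterior_fossa") {
  structure(list(
    name = "threshold_baseline",
    fit = function(training_cases) {
      function(case)
        baseline_segment(case$image, case[[region]], hu_band,
                         min_component_mm3)
    }), class = "segmenter")
}

#' Run a segmenter over a cohort
#'
#' Applies a fitted predict function to every manifest case, writing one
#' predicted mask per case id; a case whose inputs fail to load is logged
#' and skipped.
#'
#' @param predict_fn function(case) -> `structure_mask` (from a
#'   `segmenter`'s `fit`).
#' @param manifest data.frame from [read_manifest()].
#' @param out_dir directory for `<case_id>.nii.gz` predictions.
#' @return data.frame log: `case_id`, `ok`, `message`, `path`; attribute
#'   `n_failed` carries the failure count.
#' @export
run_segmenter_over_cohort <- function(predict_fn, manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$case_id[i]
    path <- file.path(out_dir, paste0(id, ".nii.gz"))
    res <- tryCatch({
      case <- load_case(manifest[i, ])
      write_mask(predict_fn(case), path)
      data.frame(case_id = id, ok = TRUE, message = "", path = path,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(case_id = id, ok = FALSE, message = conditionMessage(e),
                 path = NA_character_, stringsAsFactors = FALSE))
    res
  })
  log <- do.call(rbind, rows)
  attr(log, "n_failed") <- sum(!log$ok)
  log
}
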