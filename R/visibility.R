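#' Ordinal contour-visibility score
#'
#' Validates a manual 4-point resection-cavity visibility score: 1 means
#' fewer than 25% of the contour's slices are clearly visible, 2 means
#' 25-50%, 3 means 50-75%, and 4 means more than 75%.  Scores are human
#' annotations supplied as input; the package never infers them from
#' images.
#'
#' @param value integer (vector) in \{1, 2, 3, 4\}; NA allowed (unscored).
#' @return The validated integer vector, classed `visibility_score`.
#' @export
visibility_score <- function(value) {
  v <- as.integer(value)
  bad <- !is.na(v) & !(v %in% 1:4)
  if (any(bad))
    stop("visibility scores must be in 1..4; got ",
         paste(unique(value[bad]), collapse = ", "))
  structure(v, class = "visibility_score")
}

#' GTV-anchored crop window
#'
#' The crop used for contrast/CNR: the axis-aligned bounding box of the GTV
#' expanded by `px_xy` voxels per side in x and y and `px_z` slices per
#' side in z, clipped to the volume extents.
#'
#' @param gtv non-empty `structure_mask`.
#' @param px_xy in-plane expansion per side, voxels (default 10).
#' @param px_z slice expansion per side (default 2).
#' @return Object of class `crop_window`: list of 1-based inclusive index
#'   ranges `i`, `j`, `k` plus the expansion used.
#' @export
crop_window <- function(gtv, px_xy = 10L, px_z = 2L) {
  if (mask_is_empty(gtv)) stop("GTV mask is empty")
  idx <- which(gtv$voxels, arr.ind = TRUE)
  dm <- dim(gtv$voxels)
  rng <- function(col, pad, n)
    c(max(1L, min(idx[, col]) - pad), min(n, max(idx[, col]) + pad))
  structure(list(i = rng(1, px_xy, dm[1]),
                 j = rng(2, px_xy, dm[2]),
                 k = rng(3, px_z, dm[3]),
                 px_xy = as.integer(px_xy), px_z = as.integer(px_z)),
            class = "crop_window")
}

# logical array marking the crop window
window_mask <- function(window, dm) {
  w <- array(FALSE, dim = dm)
  w[window$i[1]:window$i[2], window$j[1]:window$j[2],
    window$k[1]:window$k[2]] <- TRUE
  w
}

#' Background voxels of a crop window
#'
#' The voxels entering the background mean/SD: inside the window, outside
#' the GTV, and below the bone threshold (HU >= `bone_hu` marks
#' high-attenuating structures such as skull, which are omitted so a
#' bone/tissue interface is not mistaken for a visible cavity edge).
#'
#' @param volume `scalar_volume`.
#' @param gtv `structure_mask` on the same grid.
#' @param window a [crop_window()]; computed from `gtv` if missing.
#' @param bone_hu HU threshold marking bone (default 1000).
#' @return Integer vector of linear voxel indices (at least 2).
#' @export
background_voxels <- function(volume, gtv, window = NULL, bone_hu = 1000) {
  if (is.null(window)) window <- crop_window(gtv)
  sel <- window_mask(window, dim(volume$voxels)) & !gtv$voxels &
    volume$voxels < bone_hu
  idx <- which(sel)
  if (length(idx) < 2)
    stop("degenerate crop window: fewer than 2 background voxels")
  idx
}

#' Contrast and CNR of a GTV against its surrounding brain tissue
#'
#' Computes the visibility metrics over one 3D crop window:
#' \deqn{Contrast = \bar{x}_{ROI} - \bar{x}_{bkg}}
#' \deqn{CNR = Contrast / \sigma_{bkg}}
#' where \eqn{\bar{x}_{ROI}} is the mean HU within the GTV contour,
#' \eqn{\bar{x}_{bkg}} the mean and \eqn{\sigma_{bkg}} the sample standard
#' deviation of the HU within the surrounding (window minus GTV) tissue.
#' Voxels at or above `bone_hu` are omitted from both ROI and background
#' statistics.
#'
#' @inheritParams background_voxels
#' @param px_xy,px_z crop expansion per side (voxels / slices).
#' @param cnr_undefined what to do when `sigma_bkg == 0`: `"error"` or
#'   `"na"` (flag the CNR as undefined).
#' @return Object of class `visibility_metrics`: `x_roi`, `x_bkg`,
#'   `sd_bkg`, `contrast`, `cnr`, `n_roi`, `n_bkg`, `window`.
#' @export
compute_visibility_metrics <- function(volume, gtv, px_xy = 10L, px_z = 2L,
                                       bone_hu = 1000,
                                       cnr_undefined = c("error", "na")) {
  cnr_undefined <- match.arg(cnr_undefined)
  check_same_grid(volume, gtv)
  win <- crop_window(gtv, px_xy = px_xy, px_z = px_z)
  roi_hu <- volume$voxels[gtv$voxels & volume$voxels < bone_hu]
  if (length(roi_hu) < 1)
    stop("no GTV voxels below the bone threshold; ROI mean undefined")
  bkg_hu <- volume$voxels[background_voxels(volume, gtv, win, bone_hu)]
  x_roi <- mean(roi_hu)
  x_bkg <- mean(bkg_hu)
  sd_bkg <- stats::sd(bkg_hu)
  contrast <- x_roi - x_bkg
  if (sd_bkg == 0) {
    if (cnr_undefined == "error")
      stop("sigma_bkg is zero: CNR undefined")
    cnr <- NA_real_
  } else {
    cnr <- contrast / sd_bkg
  }
  structure(list(x_roi = x_roi, x_bkg = x_bkg, sd_bkg = sd_bkg,
                 contrast = contrast, cnr = cnr,
                 n_roi = length(roi_hu), n_bkg = length(bkg_hu),
                 window = win),
            class = "visibility_metrics")
}

#' @export
print.visibility_metrics <- function(x, ...) {
  cat("<visibility_metrics> contrast = ", format(x$contrast, digits = 4),
      " HU, CNR = ", format(x$cnr, digits = 4),
      " (ROI n=", x$n_roi, ", bkg n=", x$n_bkg,
      ", sigma_bkg=", format(x$sd_bkg, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Keep/exclude verdict of the visibility filter
#'
#' A case is excluded when the selected metric lies inside the closed
#' low-visibility band (band endpoints are excluded too): contrast in
#' \[-10, 10\] HU or CNR in \[-0.5, 0.1\] by default.  Values outside the
#' band indicate a visible cavity and are kept.
#'
#' @param metrics a [compute_visibility_metrics()] result, or a bare
#'   numeric value of the selected metric.
#' @param mode which metric drives the filter: `"contrast"` or `"cnr"`.
#' @param contrast_band closed exclusion band for contrast, HU.
#' @param cnr_band closed exclusion band for CNR.
#' @return `"keep"` or `"exclude"`.
#' @export
apply_visibility_filter <- function(metrics, mode = c("contrast", "cnr"),
                                    contrast_band = c(-10, 10),
                                    cnr_band = c(-0.5, 0.1)) {
  mode <- match.arg(mode)
  value <- if (inherits(metrics, "visibility_metrics")) metrics[[mode]]
           else as.numeric(metrics)
  if (is.na(value)) {
    if (mode == "cnr") stop("CNR undefined; cannot filter in cnr mode")
    stop("metric value is NA")
  }
  band <- if (mode == "contrast") contrast_band else cnr_band
  if (value >= band[1] && value <= band[2]) "exclude" else "keep"
}

#' Per-case visibility report for a cohort
#'
#' Runs the crop/metrics/filter workflow over every case and returns the
#' per-case table (the CSV the scoring CLI of the workflow emits).
#'
#' @param cases list of loaded cases (as from [load_case()] or
#'   [generate_phantom()]), each with `case_id`, `image`, `gtv`.
#' @param mode,contrast_band,cnr_band see [apply_visibility_filter()].
#' @param px_xy,px_z crop expansion.
#' @return data.frame with columns `case_id`, `n_roi`, `n_bkg`, `x_roi`,
#'   `x_bkg`, `sd_bkg`, `contrast`, `cnr`, `verdict`.
#' @export
visibility_report <- function(cases, mode = "contrast",
                              contrast_band = c(-10, 10),
                              cnr_band = c(-0.5, 0.1),
                              px_xy = 10L, px_z = 2L) {
  rows <- lapply(cases, function(cs) {
    m <- compute_visibility_metrics(cs$image, cs$gtv, px_xy = px_xy,
                                    px_z = px_z, cnr_undefined = "na")
    data.frame(case_id = cs$case_id, n_roi = m$n_roi, n_bkg = m$n_bkg,
               x_roi = m$x_roi, x_bkg = m$x_bkg, sd_bkg = m$sd_bkg,
               contrast = m$contrast, cnr = m$cnr,
               verdict = apply_visibility_filter(m, mode, contrast_band,
                                                 cnr_band),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Visibility-score summary table
#'
#' Per manual visibility score: how many cases exist before filtering and
#' how many survive the contrast and CNR filters respectively (the summary
#' layout used to choose between the two filter modes).
#'
#' @param report a [visibility_report()] data.frame.
#' @param scores integer scores (1-4, NA allowed) aligned with `report`.
#' @param contrast_band,cnr_band filter bands.
#' @return data.frame: `score`, `n`, `after_contrast`, `after_cnr`.
#' @export
score_summary_table <- function(report, scores,
                                contrast_band = c(-10, 10),
                                cnr_band = c(-0.5, 0.1)) {
  scores <- visibility_score(scores)
  keep_c <- vapply(report$contrast, apply_visibility_filter, "",
                   mode = "contrast", contrast_band = contrast_band)
  keep_n <- vapply(report$cnr, function(v) {
    if (is.na(v)) NA_character_
    else apply_visibility_filter(v, "cnr", cnr_band = cnr_band)
  }, "")
  out <- lapply(4:1, function(s) {
    sel <- !is.na(scores) & scores == s
    data.frame(score = s, n = sum(sel),
               after_contrast = sum(sel & keep_c == "keep"),
               after_cnr = sum(sel & !is.na(keep_n) & keep_n == "keep"))
  })
  do.call(rbind, out)
}
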