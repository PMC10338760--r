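#' Dice similarity coefficient
#'
#' `2|A ∩ B| / (|A| + |B|)`.  Symmetric; 1 exactly when the masks are
#' identical and non-empty; comparing two empty masks is an error (silent
#' perfection on empty predictions would hide segmenter failure).
#'
#' @param a,b `structure_mask`s on one grid.
#' @return Numeric in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) stop("DSC undefined: both masks empty")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Precision and recall of a predicted mask
#'
#' precision = |pred ∩ ref| / |pred| (undefined for an empty prediction,
#' returned as NA); recall = |pred ∩ ref| / |ref|.
#'
#' @param pred predicted `structure_mask`.
#' @param ref non-empty reference `structure_mask` on the same grid.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(pred, ref) {
  check_same_grid(pred, ref)
  if (mask_is_empty(ref)) stop("reference mask is empty")
  tp <- sum(pred$voxels & ref$voxels)
  npred <- sum(pred$voxels)
  c(precision = if (npred == 0) NA_real_ else tp / npred,
    recall = tp / sum(ref$voxels))
}

# physical coordinates (mm) of a mask's surface voxels
surface_points_mm <- function(mask) {
  surf <- cpp_surface_mask(as.logical(mask$voxels), dim(mask$voxels))
  idx <- which(array(surf, dim = dim(mask$voxels)), arr.ind = TRUE)
  voxel_to_mm(mask, idx)
}

#' Hausdorff and mean surface distance between two masks
#'
#' Surface voxels are mask voxels with at least one face-adjacent outside
#' neighbor.  Directed distances run from every surface voxel of one mask
#' to the nearest surface voxel of the other (voxel center to voxel
#' center, in mm).  HD is the maximum over both directions; MSD is the
#' mean of the two directed means.
#'
#' @param a,b non-empty `structure_mask`s on one grid.
#' @return Named numeric vector `c(hd, msd)` in mm.
#' @export
surface_distances <- function(a, b) {
  check_same_grid(a, b)
  if (mask_is_empty(a) || mask_is_empty(b))
    stop("surface distances need non-empty masks")
  pa <- surface_points_mm(a)
  pb <- surface_points_mm(b)
  dab <- cpp_directed_nn(pa, pb)
  dba <- cpp_directed_nn(pb, pa)
  c(hd = max(max(dab), max(dba)), msd = (mean(dab) + mean(dba)) / 2)
}

#' Full contour comparison for one case
#'
#' DSC, HD, MSD, precision and recall of a predicted mask against a
#' reference.  An empty prediction against a non-empty reference is a
#' recorded failure: DSC and recall 0, precision/HD/MSD `NA`.
#'
#' @param pred,ref `structure_mask`s on one grid; `ref` non-empty.
#' @param case_id,structure identifiers copied into the output row.
#' @return One-row data.frame: `case_id`, `structure`, `dsc`, `hd_mm`,
#'   `msd_mm`, `precision`, `recall`.
#' @export
compare_contours <- function(pred, ref, case_id = "", structure = "") {
  if (mask_is_empty(ref)) stop("reference mask is empty")
  if (mask_is_empty(pred)) {
    return(data.frame(case_id = case_id, structure = structure,
                      dsc = 0, hd_mm = NA_real_, msd_mm = NA_real_,
                      precision = NA_real_, recall = 0,
                      stringsAsFactors = FALSE))
  }
  pr <- precision_recall(pred, ref)
  sd_ <- surface_distances(pred, ref)
  data.frame(case_id = case_id, structure = structure,
             dsc = dice(pred, ref), hd_mm = sd_[["hd"]],
             msd_mm = sd_[["msd"]], precision = pr[["precision"]],
             recall = pr[["recall"]], stringsAsFactors = FALSE)
}

#' Cohort-level metric summary
#'
#' Mean and sample SD of each metric over a list of case comparisons,
#' plus the fraction of cases with DSC > 0.90.  A single-case summary
#' reports SD 0 with `degenerate_n = TRUE`.
#'
#' @param comparisons data.frame of [compare_contours()] rows.
#' @return List: `n`, `stats` (data.frame metric/mean/sd),
#'   `frac_dsc_gt_090`, `degenerate_n`.
#' @export
summarize_cohort <- function(comparisons) {
  if (!nrow(comparisons)) stop("no comparisons to summarize")
  metrics <- c("dsc", "hd_mm", "msd_mm", "precision", "recall")
  degenerate <- nrow(comparisons) == 1L
  stats_df <- do.call(rbind, lapply(metrics, function(m) {
    v <- comparisons[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = if (degenerate) 0 else stats::sd(v[!is.na(v)]),
               stringsAsFactors = FALSE)
  }))
  list(n = nrow(comparisons), stats = stats_df,
       frac_dsc_gt_090 = mean(comparisons$dsc > 0.90),
       degenerate_n = degenerate)
}

#' Independent two-sample t-test on a metric
#'
#' Classical equal-variance (pooled) two-sample t-test by default, with
#' two-sided p-value and a significance flag at `alpha`.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance test (default `TRUE`); `FALSE` gives
#'   Welch.
#' @return List: `t`, `p`, `significant`, `df`.
#' @export
independent_t_test <- function(x, y, alpha = 0.05, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, p = 1, significant = FALSE,
                  df = length(x) + length(y) - 2))
    stop("zero pooled variance with unequal means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha, df = unname(ht$parameter))
}
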