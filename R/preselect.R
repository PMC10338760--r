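#' Is a GTV contour continuous?
#'
#' A GTV is continuous when it forms exactly one connected component.
#' Connectivity defaults to the 26-neighborhood (face, edge and corner
#' neighbors), the most permissive standard 3D connectivity, so two regions
#' touching only diagonally still count as one contour.
#'
#' @param gtv non-empty `structure_mask`.
#' @param connectivity 26 (default) or 6.
#' @return Logical scalar.
#' @export
check_continuity <- function(gtv, connectivity = 26L) {
  if (mask_is_empty(gtv)) stop("GTV mask is empty")
  n_components(gtv, connectivity) == 1L
}

# number of connected components of a mask
n_components <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  lab <- cpp_label_components(as.logical(mask$voxels), dim(mask$voxels),
                              as.integer(connectivity))
  max(lab)
}

#' Is a GTV located within the posterior fossa?
#'
#' True when at least `min_fraction` of the GTV volume lies inside the
#' fossa mask.  The fraction threshold makes the (clinically visual)
#' location criterion automatic and testable.
#'
#' @param gtv non-empty `structure_mask`.
#' @param fossa `structure_mask` on the same grid.
#' @param min_fraction minimum contained volume fraction (default 0.95).
#' @return Logical scalar.
#' @export
check_location <- function(gtv, fossa, min_fraction = 0.95) {
  if (mask_is_empty(gtv)) stop("GTV mask is empty")
  check_same_grid(gtv, fossa)
  sum(gtv$voxels & fossa$voxels) / sum(gtv$voxels) >= min_fraction
}

#' Pre-select a cohort on continuity, location and visibility
#'
#' Applies the enabled criteria to a cohort table; an entry survives only
#' if it passes every enabled criterion.  Each removed case is attributed
#' to the first criterion it fails in the fixed order continuity ->
#' location -> visibility, so the removal counts follow the sequential
#' curation narrative while the surviving set is order-independent.
#'
#' @param entries data.frame with one row per case; required columns per
#'   criterion: `continuous` (logical), `in_fossa` (logical), and
#'   `contrast` or `cnr` (numeric) for the visibility criterion.
#' @param criteria subset of `c("continuity", "location", "visibility")`.
#' @param mode,contrast_band,cnr_band see [apply_visibility_filter()].
#' @return List: `cohort` (surviving rows), `entries` (input annotated
#'   with `selected` and `removed_by`), `removals` (named integer counts
#'   per criterion).
#' @export
preselect <- function(entries,
                      criteria = c("continuity", "location", "visibility"),
                      mode = "contrast",
                      contrast_band = c(-10, 10),
                      cnr_band = c(-0.5, 0.1)) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  order_all <- c("continuity", "location", "visibility")
  criteria <- order_all[order_all %in% criteria]
  need <- c(continuity = "continuous", location = "in_fossa",
            visibility = mode)
  for (cr in criteria)
    if (is.null(entries[[need[[cr]]]]))
      stop("criterion '", cr, "' needs column '", need[[cr]],
           "' in the cohort table")

  pass <- list()
  if ("continuity" %in% criteria) pass$continuity <- entries$continuous
  if ("location" %in% criteria) pass$location <- entries$in_fossa
  if ("visibility" %in% criteria)
    pass$visibility <- vapply(entries[[mode]], function(v)
      apply_visibility_filter(v, mode, contrast_band, cnr_band), "") == "keep"

  removed_by <- rep(NA_character_, nrow(entries))
  for (cr in criteria)
    removed_by[is.na(removed_by) & !pass[[cr]]] <- cr
  entries$selected <- is.na(removed_by)
  entries$removed_by <- removed_by
  removals <- stats::setNames(
    vapply(criteria, function(cr) sum(removed_by == cr, na.rm = TRUE), 0L),
    criteria)
  list(cohort = entries[entries$selected, , drop = FALSE],
       entries = entries, removals = removals)
}

#' Deterministic train/test split
#'
#' Shuffles the cohort under the seed and takes the first
#' `round(train_fraction * n)` cases for training (rounding half away from
#' zero).  The same seed always reproduces the same partition.
#'
#' @param case_ids character vector of case ids.
#' @param train_fraction fraction of cases for training (default 0.8).
#' @param seed integer seed.
#' @return List with `train` and `test` character vectors (disjoint, union
#'   = input).
#' @export
split_cohort <- function(case_ids, train_fraction = 0.8, seed = 1L) {
  n <- length(case_ids)
  if (n < 2) stop("cohort must have at least 2 cases to split")
  n_train <- floor(train_fraction * n + 0.5)  # round half away from zero
  if (n_train < 1 || n_train >= n)
    stop("degenerate split: ", n_train, " train of ", n)
  perm <- with_phantom_seed(seed, sample.int(n))
  list(train = sort(case_ids[perm[seq_len(n_train)]]),
       test = sort(case_ids[perm[(n_train + 1):n]]))
}

#' Build the four experiment arms (two models x two test sets)
#'
#' Model 1 trains on the full training set, model 2 on its pre-selected
#' subset; both are evaluated on the full test set and on the pre-selected
#' test set (the pre-selected test set is the intersection of the
#' pre-selected cohort with the full test set, so no test case ever
#' appears in its arm's training data).
#'
#' @param full_ids all case ids.
#' @param preselected_ids surviving case ids; must be a subset of
#'   `full_ids`.
#' @param full_test_ids the full cohort's test partition.
#' @return List of 4 arms, each `list(model, test_set, train_ids,
#'   test_ids)`, with `model` in `model1_full_training` /
#'   `model2_preselected_training` and `test_set` in `full_test` /
#'   `preselected_test`.
#' @export
build_experiment_arms <- function(full_ids, preselected_ids, full_test_ids) {
  if (!all(preselected_ids %in% full_ids))
    stop("preselected cohort is not a subset of the full cohort")
  if (!all(full_test_ids %in% full_ids))
    stop("test set is not a subset of the full cohort")
  full_train <- setdiff(full_ids, full_test_ids)
  pre_train <- intersect(preselected_ids, full_train)
  pre_test <- intersect(preselected_ids, full_test_ids)
  arms <- list()
  for (model in c("model1_full_training", "model2_preselected_training")) {
    train <- if (model == "model1_full_training") full_train else pre_train
    for (ts in c("full_test", "preselected_test")) {
      test <- if (ts == "full_test") full_test_ids else pre_test
      if (length(intersect(train, test)))
        stop("train/test leakage in arm ", model, " x ", ts)
      arms[[paste(model, ts, sep = ".")]] <-
        list(model = model, test_set = ts, train_ids = train,
             test_ids = test)
    }
  }
  arms
}
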