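#' Margin specification for GTV -> CTV expansion
#'
#' The clinical rule: a 15 mm (1.5 cm) anatomic expansion of the GTV,
#' confined to the brain and excluding the brainstem, with the margin
#' reduced to 5 mm (0.5 cm) in the direction of the brainstem when the GTV
#' is immediately adjacent to it.
#'
#' @param nominal_mm nominal expansion margin, mm (default 15).
#' @param reduced_mm reduced margin toward the brainstem, mm (default 5);
#'   must satisfy 0 < reduced <= nominal.
#' @param adjacency_mm GTV-to-brainstem distance at or below which the
#'   reduction is triggered, mm (default 2, about one slice).
#' @return Object of class `margin_spec`.
#' @export
margin_spec <- function(nominal_mm = 15, reduced_mm = 5, adjacency_mm = 2) {
  if (!(reduced_mm > 0 && reduced_mm <= nominal_mm))
    stop("need 0 < reduced_mm <= nominal_mm")
  if (adjacency_mm < 0) stop("adjacency_mm must be >= 0")
  structure(list(nominal_mm = nominal_mm, reduced_mm = reduced_mm,
                 adjacency_mm = adjacency_mm),
            class = "margin_spec")
}

#' Euclidean distance field from a mask
#'
#' Per-voxel distance in mm from the voxel center to the nearest mask
#' voxel center (0 inside the mask), computed with an exact separable
#' distance transform that honours anisotropic spacing.
#'
#' @param mask non-empty `structure_mask`.
#' @return 3D numeric array of distances in mm, same shape as the mask.
#' @export
distance_from <- function(mask) {
  if (mask_is_empty(mask)) stop("cannot take distances from an empty mask")
  d2 <- cpp_edt_sq(as.logical(mask$voxels), dim(mask$voxels), mask$spacing)
  array(sqrt(d2), dim = dim(mask$voxels))
}

#' Is the GTV immediately adjacent to the brainstem?
#'
#' True when the minimum distance from any GTV voxel to the nearest
#' brainstem voxel is at most `adjacency_mm`.
#'
#' @param gtv,brainstem non-empty `structure_mask`s on one grid.
#' @param adjacency_mm trigger distance in mm.
#' @return Logical scalar.
#' @export
is_adjacent <- function(gtv, brainstem, adjacency_mm = 2) {
  if (mask_is_empty(gtv) || mask_is_empty(brainstem))
    stop("adjacency needs non-empty masks")
  check_same_grid(gtv, brainstem)
  d <- distance_from(brainstem)
  min(d[gtv$voxels]) <= adjacency_mm
}

#' Expand a GTV to an anatomically constrained CTV
#'
#' Without brainstem adjacency the CTV is every brain voxel within the
#' nominal margin of the GTV, minus the brainstem.  When the GTV is
#' adjacent to the brainstem the allowed margin varies spatially,
#' \deqn{m(v) = reduced + (nominal - reduced) \cdot
#'       \min(1, d_{bs}(v) / nominal),}
#' i.e. 5 mm at the brainstem surface, recovering linearly to the full
#' 15 mm at and beyond 15 mm from the brainstem.  The GTV itself (outside
#' the brainstem) is always retained.  If excluding the brainstem would
#' remove GTV voxels, those voxels are excluded and a warning reports the
#' overlap volume.
#'
#' @param gtv non-empty `structure_mask`, contained in `brain`.
#' @param brain `structure_mask` confining the CTV.
#' @param brainstem `structure_mask` excluded from the CTV (may be empty:
#'   no exclusion, no reduction).
#' @param spec a [margin_spec()].
#' @return A `structure_mask` labelled `"ctv"` satisfying
#'   GTV - brainstem  ⊆  CTV  ⊆  brain, CTV ∩ brainstem = ∅.
#' @export
expand_gtv_to_ctv <- function(gtv, brain, brainstem, spec = margin_spec()) {
  if (mask_is_empty(gtv)) stop("GTV mask is empty")
  check_same_grid(gtv, brain)
  check_same_grid(gtv, brainstem)
  if (any(gtv$voxels & !brain$voxels))
    stop("GTV extends outside the brain mask")
  overlap <- gtv$voxels & brainstem$voxels
  if (any(overlap))
    warning("GTV overlaps the brainstem by ",
            format(sum(overlap) * prod(gtv$spacing), digits = 4),
            " mm^3; overlapping voxels are excluded from the CTV")

  d_gtv <- distance_from(gtv)
  adjacent <- !mask_is_empty(brainstem) &&
    is_adjacent(gtv, brainstem, spec$adjacency_mm)
  if (adjacent) {
    d_bs <- distance_from(brainstem)
    m <- spec$reduced_mm + (spec$nominal_mm - spec$reduced_mm) *
      pmin(1, d_bs / spec$nominal_mm)
    ctv <- d_gtv <= m
  } else {
    ctv <- d_gtv <= spec$nominal_mm
  }
  ctv <- (ctv & brain$voxels & !brainstem$voxels) |
    (gtv$voxels & !brainstem$voxels)
  structure_mask(ctv, gtv, label = "ctv")
}
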