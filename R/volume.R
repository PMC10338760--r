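#' @useDynLib cavityqa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' CT volume in Hounsfield units
#'
#' Container for a 3D CT image: a voxel array in Hounsfield units (HU) plus
#' the physical grid it lives on.  Axis order is (x, y, z) with z the slice
#' axis; the physical position of voxel `(i, j, k)` (1-based) is its center,
#' `origin + (c(i, j, k) - 1) * spacing`, in mm.  All distances in the
#' package are computed in mm from `spacing`, never in voxel counts.
#'
#' @param voxels 3D numeric array of HU values; all values must be finite.
#' @param spacing length-3 numeric, voxel spacing (dx, dy, dz) in mm,
#'   strictly positive.
#' @param origin length-3 numeric, physical position (mm) of the center of
#'   voxel (1, 1, 1).
#' @return An object of class `scalar_volume` with fields `voxels`,
#'   `spacing`, `origin`.
#' @export
scalar_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array, got ", length(dim(voxels)), " dims")
  if (!all(is.finite(voxels)))
    stop("HU values must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values in mm")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' Binary structure mask on a volume grid
#'
#' A boolean voxel mask (GTV, brain, brainstem, posterior fossa, CTV, ...)
#' bound to the grid of a [scalar_volume()]: same array shape, spacing and
#' origin.  The empty mask is valid; use [mask_is_empty()] to query.
#'
#' @param voxels 3D logical (or coercible 0/1) array; any nonzero value is
#'   treated as inside.
#' @param grid a `scalar_volume`, `structure_mask`, or list with `spacing`
#'   and `origin`, defining the grid; its shape must match `voxels` when it
#'   carries one.
#' @param label free-text structure name.
#' @return An object of class `structure_mask` with fields `voxels`
#'   (logical array), `spacing`, `origin`, `label`.
#' @export
structure_mask <- function(voxels, grid, label = "structure") {
  if (length(dim(voxels)) != 3L)
    stop("mask 'voxels' must be a 3D array")
  gv <- grid$voxels
  if (!is.null(gv) && !identical(dim(voxels), dim(gv)))
    stop("mask shape (", paste(dim(voxels), collapse = "x"),
         ") does not match grid shape (", paste(dim(gv), collapse = "x"), ")")
  lv <- array(as.logical(voxels != 0), dim = dim(voxels))
  structure(list(voxels = lv, spacing = as.numeric(grid$spacing),
                 origin = as.numeric(grid$origin), label = as.character(label)),
            class = "structure_mask")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm\n  HU range [", round(min(x$voxels), 1), ", ",
      round(max(x$voxels), 1), "]\n", sep = "")
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat("<structure_mask> '", x$label, "', ",
      paste(dim(x$voxels), collapse = " x "), " grid, ",
      sum(x$voxels), " voxels inside (",
      format(mask_volume_mm3(x), digits = 4), " mm^3)\n", sep = "")
  invisible(x)
}

#' Is a mask empty?
#' @param mask a `structure_mask`.
#' @return Logical scalar.
#' @export
mask_is_empty <- function(mask) !any(mask$voxels)

#' Physical volume of a mask in mm^3
#' @param mask a `structure_mask`.
#' @return Numeric scalar, voxel count times voxel volume.
#' @export
mask_volume_mm3 <- function(mask) sum(mask$voxels) * prod(mask$spacing)

#' Physical coordinates of voxel indices
#'
#' Maps 1-based voxel indices to the physical (mm) coordinates of the voxel
#' centers: `origin + (index - 1) * spacing`.
#'
#' @param obj a `scalar_volume` or `structure_mask` (source of spacing and
#'   origin).
#' @param index integer matrix with 3 columns (i, j, k), or length-3 vector.
#' @return Numeric matrix with 3 columns, coordinates in mm.
#' @export
voxel_to_mm <- function(obj, index) {
  if (is.null(dim(index))) index <- matrix(index, ncol = 3)
  sweep(sweep(index - 1, 2, obj$spacing, "*"), 2, obj$origin, "+")
}

# shared-grid check used by every pairwise mask operation
check_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("masks are on different grids: shapes ",
         paste(dim(a$voxels), collapse = "x"), " vs ",
         paste(dim(b$voxels), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > tol ||
      max(abs(a$origin - b$origin)) > tol)
    stop("masks are on different grids (spacing/origin mismatch)")
  invisible(TRUE)
}
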