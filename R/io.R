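#' Read a CT volume from NIfTI
#'
#' Reads a 3D NIfTI-1 image as a [scalar_volume()].  Spacing is taken from
#' the header `pixdim`, the origin from the qform/sform offset; voxel values
#' are interpreted as HU after the header's slope/intercept scaling (applied
#' by the NIfTI reader) and are not rescaled further.
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @return A `scalar_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive spacing in header of ", path)
  hdr <- RNifti::niftiHeader(img)
  org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  vox <- as.array(img)
  attributes(vox) <- list(dim = d)
  scalar_volume(vox, spacing = sp, origin = org)
}

#' Write a CT volume to NIfTI
#'
#' @param volume a `scalar_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  write_nifti_array(volume$voxels, volume$spacing, volume$origin, path,
                    datatype = "double")
}

#' Read a structure mask bound to a volume grid
#'
#' Any nonzero voxel value becomes `TRUE`.  The file's array shape must
#' match the grid's.
#'
#' @param path path to a NIfTI mask file.
#' @param grid the `scalar_volume` (or compatible object) the mask lives on.
#' @param label structure name recorded on the mask.
#' @return A `structure_mask` on `grid`.
#' @export
read_mask <- function(path, grid, label = "structure") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D mask, got ", length(d), "D")
  if (!identical(as.integer(d), as.integer(dim(grid$voxels))))
    stop("mask shape (", paste(d, collapse = "x"),
         ") does not match grid shape (",
         paste(dim(grid$voxels), collapse = "x"), "): ", path)
  vox <- as.array(img)
  attributes(vox) <- list(dim = d)
  structure_mask(vox, grid, label = label)
}

#' Write a structure mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit (0/1) with the grid's spacing and
#' origin in the header; a written mask round-trips through [read_mask()]
#' to an identical mask.
#'
#' @param mask a `structure_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_nifti_array(array(as.integer(mask$voxels), dim = dim(mask$voxels)),
                    mask$spacing, mask$origin, path, datatype = "uint8")
}

write_nifti_array <- function(arr, spacing, origin, path, datatype) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  xf <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with fixed columns `case_id`, `image`, `gtv`,
#' `brain`, `brainstem`, `posterior_fossa`; path columns are resolved
#' relative to the manifest's directory unless absolute.
#'
#' @param path manifest CSV path.
#' @return A data.frame, one row per case, with absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "image", "gtv", "brain", "brainstem", "posterior_fossa")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(man$case_id))
    stop("duplicate case ids in manifest")
  if (any(!nzchar(man$case_id))) stop("empty case id in manifest")
  base <- dirname(normalizePath(path))
  for (col in setdiff(need, "case_id")) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
  }
  man
}

#' Load one manifest case into memory
#'
#' @param entry one row of a [read_manifest()] data.frame.
#' @return List with `case_id`, `image` (`scalar_volume`) and masks `gtv`,
#'   `brain`, `brainstem`, `posterior_fossa` (`structure_mask` each).
#' @export
load_case <- function(entry) {
  vol <- read_volume(entry$image)
  list(case_id = entry$case_id,
       image = vol,
       gtv = read_mask(entry$gtv, vol, "gtv"),
       brain = read_mask(entry$brain, vol, "brain"),
       brainstem = read_mask(entry$brainstem, vol, "brainstem"),
       posterior_fossa = read_mask(entry$posterior_fossa, vol,
                                   "posterior_fossa"))
}
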