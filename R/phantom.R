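#' Specification of a synthetic CT head phantom
#'
#' Defines one phantom: an ellipsoidal brain of Gaussian-noise HU inside a
#' constant-HU skull shell, a posterior-fossa subregion, a cylindrical
#' brainstem, and a resection cavity (the GTV) whose mean-HU offset from
#' brain is the programmed contrast.  The seed fully determines the output.
#'
#' Defaults emulate the cohort the pipeline targets: brain mean 35 HU (the
#' level of the standard brain display window), 2.5 mm slices with 1 mm
#' in-plane pixels, skull well above the 1000 HU bone threshold.
#'
#' @param shape volume dimensions (nx, ny, nz).
#' @param spacing voxel spacing in mm.
#' @param brain_mean_hu mean HU of normal brain tissue.
#' @param sigma_hu standard deviation of the iid Gaussian HU noise within
#'   the brain (and cavity).
#' @param skull_hu constant HU of the skull shell; must be >= 1000 so the
#'   bone-exclusion rule fires on it.
#' @param delta_hu programmed cavity contrast: cavity mean = brain mean +
#'   `delta_hu`.  May be negative, zero or positive.
#' @param cavity_radius_mm radius of each cavity ball, > 0.
#' @param n_components number of disjoint cavity balls (1 = continuous GTV).
#' @param in_fossa place the cavity inside the posterior fossa (`TRUE`) or
#'   supratentorially (`FALSE`).
#' @param cavity_center_mm optional explicit cavity center (mm); overrides
#'   `in_fossa` placement.
#' @param edge_blur_mm optional Gaussian softening of the cavity edge
#'   (0 = hard edge).
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 64L),
                         spacing = c(1, 1, 2.5),
                         brain_mean_hu = 35,
                         sigma_hu = 5,
                         skull_hu = 1200,
                         delta_hu = 40,
                         cavity_radius_mm = 10,
                         n_components = 1L,
                         in_fossa = TRUE,
                         cavity_center_mm = NULL,
                         edge_blur_mm = 0,
                         seed = 1L) {
  if (skull_hu < 1000) stop("skull_hu must be >= 1000")
  if (cavity_radius_mm <= 0) stop("cavity_radius_mm must be > 0")
  if (n_components < 1) stop("n_components must be >= 1")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 brain_mean_hu = brain_mean_hu, sigma_hu = sigma_hu,
                 skull_hu = skull_hu, delta_hu = delta_hu,
                 cavity_radius_mm = cavity_radius_mm,
                 n_components = as.integer(n_components),
                 in_fossa = isTRUE(in_fossa),
                 cavity_center_mm = cavity_center_mm,
                 edge_blur_mm = edge_blur_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# evaluate code under a seed, restoring the caller's RNG state
with_phantom_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic CT head phantom
#'
#' Brain voxels are iid Normal(brain mean, sigma^2); cavity voxels are
#' Normal(brain mean + delta, sigma^2); the skull is a closed constant-HU
#' shell around the brain; everything outside is air (-1000 HU).  The
#' brainstem is a cylinder anterior to the posterior fossa; the posterior
#' fossa is the inferior-posterior part of the brain ellipsoid.  Identical
#' seeds give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case`: list with `case_id` (empty
#'   until assigned by [generate_cohort()]), `image` (`scalar_volume`),
#'   masks `gtv`, `brain`, `brainstem`, `posterior_fossa`
#'   (`structure_mask`), and `spec` (the truth used).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$shape
  sp <- spec$spacing
  extent <- (dm - 1) * sp
  ctr <- extent / 2

  # physical voxel-center coordinates, one vector per axis
  xs <- (seq_len(dm[1]) - 1) * sp[1]
  ys <- (seq_len(dm[2]) - 1) * sp[2]
  zs <- (seq_len(dm[3]) - 1) * sp[3]
  # brain ellipsoid semi-axes scale with the volume so small test grids work
  semi <- pmin(c(52, 58, 65), 0.42 * extent)

  xn <- (xs - ctr[1]) / semi[1]
  yn <- (ys - ctr[2]) / semi[2]
  zn <- (zs - ctr[3]) / semi[3]
  rn2 <- outer(outer(xn^2, yn^2, "+"), zn^2, "+")
  brain <- rn2 <= 1
  # thick closed shell: crop windows that overshoot the brain land in bone
  # (handled by the HU>=1000 exclusion), not in air; air fills the corners
  skull <- rn2 > 1 & rn2 <= 2.6

  # posterior fossa: inferior-posterior sector of the brain ellipsoid
  # (+y posterior, +z superior)
  post <- outer(outer(rep(TRUE, dm[1]), ys >= ctr[2], "&"),
                zs <= ctr[3] - semi[3] / 3, "&")
  fossa <- brain & post

  # brainstem: z-aligned cylinder anterior-inferior to the fossa
  bs_r <- min(7.5, 0.12 * extent[1])
  bs_y <- ctr[2] - 0.31 * semi[2]
  r2xy <- outer((xs - ctr[1])^2, (ys - bs_y)^2, "+")
  bs_z <- zs >= ctr[3] - 0.7 * semi[3] & zs <= ctr[3] - 0.05 * semi[3]
  brainstem <- outer(r2xy <= bs_r^2, bs_z, "&") & brain

  # cavity centers
  if (!is.null(spec$cavity_center_mm)) {
    ctr_cav <- matrix(spec$cavity_center_mm, ncol = 3)
  } else if (spec$in_fossa) {
    # deep enough below the tentorial cut that the whole ball is in-fossa
    r <- spec$cavity_radius_mm
    base <- c(ctr[1],
              ctr[2] + max(0.34 * semi[2], r + 3),
              ctr[3] - max(0.54 * semi[3], semi[3] / 3 + r + 3))
    ctr_cav <- matrix(base, ncol = 3)
  } else {
    base <- c(ctr[1], ctr[2], ctr[3] + 0.46 * semi[3])
    ctr_cav <- matrix(base, ncol = 3)
  }
  if (spec$n_components > 1) {
    # extra disjoint balls offset along x
    offs <- (seq_len(spec$n_components) - 1)
    offs <- ifelse(offs %% 2 == 0, 1, -1) * ceiling(offs / 2) *
      (2 * spec$cavity_radius_mm + 4)
    ctr_cav <- cbind(ctr_cav[1, 1] + offs,
                     rep(ctr_cav[1, 2], spec$n_components),
                     rep(ctr_cav[1, 3], spec$n_components))
  }

  gtv <- array(FALSE, dim = dm)
  dist2_cav <- array(Inf, dim = dm)
  for (b in seq_len(nrow(ctr_cav))) {
    d2 <- outer(outer((xs - ctr_cav[b, 1])^2, (ys - ctr_cav[b, 2])^2, "+"),
                (zs - ctr_cav[b, 3])^2, "+")
    gtv <- gtv | (d2 <= spec$cavity_radius_mm^2)
    dist2_cav <- pmin(dist2_cav, d2)
  }
  if (!any(gtv)) stop("impossible geometry: cavity contains no voxel")
  if (any(gtv & !brain))
    stop("cavity collides with skull or extends outside the brain")
  if (any(gtv & brainstem))
    stop("impossible geometry: cavity overlaps the brainstem")

  vox <- with_phantom_seed(spec$seed, {
    v <- array(-1000, dim = dm)
    v[skull] <- spec$skull_hu
    nb <- sum(brain)
    v[brain] <- spec$brain_mean_hu + spec$sigma_hu * stats::rnorm(nb)
    if (spec$edge_blur_mm > 0) {
      sd_surface <- sqrt(dist2_cav) - spec$cavity_radius_mm  # >0 outside
      w <- stats::pnorm(-sd_surface / spec$edge_blur_mm)
      v[brain] <- v[brain] + spec$delta_hu * w[brain]
    } else {
      v[gtv] <- v[gtv] + spec$delta_hu
    }
    v
  })

  vol <- scalar_volume(vox, spacing = sp)
  out <- list(case_id = "",
              image = vol,
              gtv = structure_mask(gtv, vol, "gtv"),
              brain = structure_mask(brain, vol, "brain"),
              brainstem = structure_mask(brainstem, vol, "brainstem"),
              posterior_fossa = structure_mask(fossa, vol, "posterior_fossa"),
              spec = spec)
  class(out) <- "phantom_case"
  out
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> ", if (nzchar(x$case_id)) x$case_id else "(unnamed)",
      ": delta_hu=", x$spec$delta_hu, ", sigma=", x$spec$sigma_hu,
      ", components=", x$spec$n_components,
      ", in_fossa=", x$spec$in_fossa, "\n", sep = "")
  invisible(x)
}

#' Generate a phantom cohort on disk
#'
#' Expands a regime table into individual phantoms, writes each case's
#' image and structure masks as NIfTI under `out_dir/<case_id>/`, and
#' writes a cohort manifest plus a truth table with the programmed
#' parameters.  Per-case seeds are derived deterministically from the
#' master seed, so the same master seed reproduces the cohort
#' byte-identically.
#'
#' @param regimes a data.frame with one row per regime and columns `n`
#'   (cases in the regime) and any of `delta_hu`, `sigma_hu`,
#'   `n_components`, `in_fossa`, `cavity_radius_mm` overriding
#'   [phantom_spec()] defaults.
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param shape,spacing grid passed to every [phantom_spec()].
#' @return Invisibly, a list with `manifest` (path to manifest.csv),
#'   `truth` (path to truth.csv) and `cases` (character ids).
#' @export
generate_cohort <- function(regimes, out_dir, seed = 1L,
                            shape = c(128L, 128L, 64L),
                            spacing = c(1, 1, 2.5)) {
  if (!is.data.frame(regimes) || is.null(regimes$n))
    stop("'regimes' must be a data.frame with an 'n' column")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- regimes[rep(seq_len(nrow(regimes)), regimes$n), , drop = FALSE]
  ncase <- nrow(rows)
  ids <- sprintf("case_%03d", seq_len(ncase))

  man <- data.frame(case_id = ids, image = "", gtv = "", brain = "",
                    brainstem = "", posterior_fossa = "",
                    stringsAsFactors = FALSE)
  truth <- data.frame(case_id = ids, delta_hu = NA_real_, sigma_hu = NA_real_,
                      n_components = NA_integer_, in_fossa = NA,
                      seed = NA_integer_, stringsAsFactors = FALSE)

  for (i in seq_len(ncase)) {
    args <- list(shape = shape, spacing = spacing,
                 seed = (seed %% 100000L) * 10007L + i * 7919L)
    for (f in c("delta_hu", "sigma_hu", "n_components", "in_fossa",
                "cavity_radius_mm"))
      if (!is.null(rows[[f]])) args[[f]] <- rows[[f]][i]
    spec <- do.call(phantom_spec, args)
    case <- generate_phantom(spec)
    cdir <- file.path(out_dir, ids[i])
    dir.create(cdir, showWarnings = FALSE)
    write_volume(case$image, file.path(cdir, "image.nii.gz"))
    for (s in c("gtv", "brain", "brainstem", "posterior_fossa"))
      write_mask(case[[s]], file.path(cdir, paste0(s, ".nii.gz")))
    man[i, -1] <- file.path(ids[i],
                            c("image.nii.gz", "gtv.nii.gz", "brain.nii.gz",
                              "brainstem.nii.gz", "posterior_fossa.nii.gz"))
    truth[i, -1] <- list(spec$delta_hu, spec$sigma_hu, spec$n_components,
                         spec$in_fossa, spec$seed)
  }
  man_path <- file.path(out_dir, "manifest.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  utils::write.csv(truth, truth_path, row.names = FALSE)
  invisible(list(manifest = man_path, truth = truth_path, cases = ids))
}
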