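# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (enumeration, flood fill, all-pairs loops) so they
# check the package's fast paths without sharing code with them.

unit_volume <- function(dm, spacing = c(1, 1, 1), hu = 0) {
  scalar_volume(array(hu, dim = dm), spacing = spacing)
}

mask_from <- function(arr, spacing = c(1, 1, 1)) {
  structure_mask(arr, list(spacing = spacing, origin = c(0, 0, 0),
                           voxels = array(0, dim = dim(arr))))
}

ball_mask <- function(dm, center, radius, spacing = c(1, 1, 1)) {
  idx <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]),
                               seq_len(dm[3])))
  pts <- sweep(idx - 1, 2, spacing, "*")
  d2 <- rowSums(sweep(pts, 2, center, "-")^2)
  mask_from(array(d2 <= radius^2, dim = dm), spacing)
}

random_mask <- function(dm, p = 0.15, spacing = c(1, 1, 1)) {
  repeat {
    arr <- array(stats::runif(prod(dm)) < p, dim = dm)
    if (any(arr)) return(mask_from(arr, spacing))
  }
}

# flood fill over an explicit neighbor list: continuity oracle
oracle_n_components <- function(arr, connectivity = 26) {
  dm <- dim(arr)
  seen <- array(FALSE, dim = dm)
  idx <- which(arr, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  ncomp <- 0
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (seen[v[1], v[2], v[3]]) next
    ncomp <- ncomp + 1
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > dm)) next
        if (arr[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  ncomp
}

# all-pairs distance field oracle
oracle_distance_field <- function(arr, spacing) {
  dm <- dim(arr)
  tgt <- sweep(which(arr, arr.ind = TRUE) - 1, 2, spacing, "*")
  all_idx <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]),
                                   seq_len(dm[3])))
  pts <- sweep(all_idx - 1, 2, spacing, "*")
  d <- apply(pts, 1, function(p) sqrt(min(colSums((t(tgt) - p)^2))))
  out <- array(NA_real_, dim = dm)
  out[all_idx] <- d
  out
}

# surface voxels by explicit face-neighbor inspection
oracle_surface_idx <- function(arr) {
  dm <- dim(arr)
  idx <- which(arr, arr.ind = TRUE)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  on_surface <- vapply(seq_len(nrow(idx)), function(r) {
    v <- idx[r, ]
    for (o in seq_len(6)) {
      nb <- v + offs[o, ]
      if (any(nb < 1) || any(nb > dm)) return(TRUE)
      if (!arr[nb[1], nb[2], nb[3]]) return(TRUE)
    }
    FALSE
  }, logical(1))
  idx[on_surface, , drop = FALSE]
}

oracle_surface_distances <- function(a, b, spacing) {
  pa <- sweep(oracle_surface_idx(a) - 1, 2, spacing, "*")
  pb <- sweep(oracle_surface_idx(b) - 1, 2, spacing, "*")
  dmat <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  dmat <- sqrt(pmax(dmat, 0))
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  c(hd = max(max(dab), max(dba)), msd = (mean(dab) + mean(dba)) / 2)
}

# small phantom grid used throughout the experiment-level tests: keeps
# full runs fast while leaving room for the cavity and margins
small_shape <- c(64L, 64L, 32L)
small_spacing <- c(2, 2, 2.5)

small_phantom <- function(delta_hu = 40, sigma_hu = 2, seed = 1,
                          n_components = 1L, in_fossa = TRUE,
                          cavity_radius_mm = 8, ...) {
  generate_phantom(phantom_spec(shape = small_shape, spacing = small_spacing,
                                delta_hu = delta_hu, sigma_hu = sigma_hu,
                                n_components = n_components,
                                in_fossa = in_fossa,
                                cavity_radius_mm = cavity_radius_mm,
                                seed = seed, ...))
}
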