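test_that("distance fields honour anisotropic spacing", {
  dm <- c(7, 7, 7)
  m <- array(FALSE, dim = dm); m[4, 4, 4] <- TRUE
  d <- distance_from(mask_from(m, spacing = c(1, 1, 2.5)))
  expect_equal(d[4, 4, 4], 0)
  expect_equal(d[5, 4, 4], 1)
  expect_equal(d[4, 4, 5], 2.5)
  expect_equal(d[5, 5, 5], sqrt(1 + 1 + 2.5^2))
  expect_error(distance_from(mask_from(array(FALSE, dm))), "empty")
})

test_that("distance fields equal the all-pairs oracle on random grids", {
  set.seed(7)
  for (i in 1:6) {
    sp <- runif(3, 0.5, 3)
    m <- random_mask(c(10, 11, 12), p = 0.05, spacing = sp)
    expect_equal(distance_from(m),
                 oracle_distance_field(m$voxels, sp), tolerance = 1e-12)
  }
})

test_that("adjacency uses a <= rule on the minimum distance", {
  dm <- c(40, 20, 20)
  bs <- array(FALSE, dim = dm); bs[1:5, , ] <- TRUE
  touch <- array(FALSE, dim = dm); touch[6:8, 8:12, 8:12] <- TRUE
  far <- array(FALSE, dim = dm); far[36:38, 8:12, 8:12] <- TRUE
  exact2 <- array(FALSE, dim = dm); exact2[7:9, 8:12, 8:12] <- TRUE
  bsm <- mask_from(bs)
  expect_true(is_adjacent(mask_from(touch), bsm, 2))
  expect_false(is_adjacent(mask_from(far), bsm, 2))   # 30 mm away
  expect_true(is_adjacent(mask_from(exact2), bsm, 2)) # nearest exactly 2.0
  expect_false(is_adjacent(mask_from(exact2), bsm, 1.99))
  expect_error(is_adjacent(mask_from(array(FALSE, dm)), bsm), "non-empty")
})

test_that("an unconstrained single-voxel GTV expands to the exact ball", {
  dm <- c(41, 41, 41)
  gtv <- array(FALSE, dim = dm); gtv[21, 21, 21] <- TRUE
  brain <- mask_from(array(TRUE, dim = dm))
  none <- mask_from(array(FALSE, dim = dm))
  ctv <- expand_gtv_to_ctv(mask_from(gtv), brain, none,
                           margin_spec(nominal_mm = 15))
  # brute-force lattice ball: centers within 15 mm of voxel (21,21,21)
  idx <- as.matrix(expand.grid(1:41, 1:41, 1:41))
  inside <- rowSums(sweep(idx, 2, c(21, 21, 21), "-")^2) <= 15^2
  expected <- array(FALSE, dim = dm); expected[idx[inside, ]] <- TRUE
  expect_identical(ctv$voxels, expected)
})

test_that("the CTV is confined to brain and excludes the brainstem", {
  ph <- small_phantom(seed = 21)
  ctv <- expand_gtv_to_ctv(ph$gtv, ph$brain, ph$brainstem)
  expect_false(any(ctv$voxels & !ph$brain$voxels))
  expect_false(any(ctv$voxels & ph$brainstem$voxels))
  expect_true(all(ctv$voxels[ph$gtv$voxels & !ph$brainstem$voxels]))
  # clipping really engaged: the unconstrained ball would leave the brain
  d <- distance_from(ph$gtv)
  expect_true(any(d <= 15 & !ph$brain$voxels))
})

test_that("adjacency reduces the margin at the brainstem and restores it far away", {
  dm <- c(60, 40, 40)
  brain <- mask_from(array(TRUE, dim = dm))
  bs <- array(FALSE, dim = dm); bs[1:6, , ] <- TRUE
  gtv <- array(FALSE, dim = dm); gtv[8:12, 16:24, 16:24] <- TRUE
  gtvm <- mask_from(gtv); bsm <- mask_from(bs)
  expect_true(is_adjacent(gtvm, bsm, 2))
  ctv <- expand_gtv_to_ctv(gtvm, brain, bsm)
  d_bs <- distance_from(bsm)
  d_gtv <- distance_from(gtvm)
  # voxels one voxel off the brainstem: allowed margin is m(1) = 5 + 10/15
  at_surface <- ctv$voxels & d_bs <= 1 + 1e-9
  expect_true(any(at_surface))
  expect_true(all(d_gtv[at_surface] <= 5 + 10 / 15 + 1e-9))
  # far from the brainstem the full 15 mm reach returns
  far_reach <- d_gtv <= 15 & d_bs >= 15
  expect_true(any(far_reach))
  expect_true(all(ctv$voxels[far_reach]))
  # and the CTV matches the declared spatially varying margin everywhere
  m <- 5 + 10 * pmin(1, d_bs / 15)
  expected <- (d_gtv <= m | gtv) & !bs
  expect_identical(ctv$voxels, array(expected, dim = dm))
})

test_that("margins are monotone in the nominal margin and the brainstem", {
  ph <- small_phantom(seed = 33)
  small_ <- expand_gtv_to_ctv(ph$gtv, ph$brain, ph$brainstem,
                              margin_spec(nominal_mm = 10))
  large_ <- expand_gtv_to_ctv(ph$gtv, ph$brain, ph$brainstem,
                              margin_spec(nominal_mm = 15))
  expect_true(all(large_$voxels[small_$voxels]))

  grown <- structure_mask(
    distance_from(ph$brainstem) <= 4, ph$image, "brainstem_grown")
  base <- expand_gtv_to_ctv(ph$gtv, ph$brain, ph$brainstem)
  shr <- expand_gtv_to_ctv(ph$gtv, ph$brain, grown)
  expect_true(all(base$voxels[shr$voxels]))
})

test_that("GTV voxels inside the brainstem are excluded with a warning", {
  dm <- c(20, 20, 20)
  brain <- mask_from(array(TRUE, dim = dm))
  bs <- array(FALSE, dim = dm); bs[1:10, , ] <- TRUE
  gtv <- array(FALSE, dim = dm); gtv[9:12, 9:12, 9:12] <- TRUE
  expect_warning(
    ctv <- expand_gtv_to_ctv(mask_from(gtv), brain, mask_from(bs)),
    "overlaps the brainstem")
  expect_false(any(ctv$voxels & bs))
  expect_true(all(ctv$voxels[gtv & !bs]))
})

test_that("containment invariants hold on randomized geometries", {
  set.seed(55)
  dm <- c(24, 24, 24)
  for (i in 1:25) {
    sp <- sample(list(c(1, 1, 1), c(1, 1, 2.5), c(2, 2, 2)), 1)[[1]]
    brain_arr <- array(FALSE, dim = dm)
    brain_arr[3:22, 3:22, 3:22] <- TRUE
    ctr <- runif(3, 8, 16) * sp
    gtv <- ball_mask(dm, ctr, runif(1, 2, 5), sp)
    gtv <- mask_from(gtv$voxels & brain_arr, sp)
    if (mask_is_empty(gtv)) next
    bs_arr <- array(FALSE, dim = dm)
    bs_lo <- sample(3:18, 1)
    bs_arr[bs_lo:min(22, bs_lo + 3), 3:22, 3:22] <- TRUE
    bs <- mask_from(bs_arr & !gtv$voxels, sp)
    brain <- mask_from(brain_arr, sp)
    spec <- margin_spec(nominal_mm = runif(1, 6, 15),
                        reduced_mm = runif(1, 2, 5))
    ctv <- expand_gtv_to_ctv(gtv, brain, bs, spec)
    expect_true(all(ctv$voxels[gtv$voxels & !bs$voxels]))
    expect_false(any(ctv$voxels & !brain$voxels))
    expect_false(any(ctv$voxels & bs$voxels))
  }
})

test_that("margin specs validate their bounds", {
  expect_error(margin_spec(reduced_mm = 20), "reduced_mm <= nominal")
  expect_error(margin_spec(reduced_mm = 0), "reduced_mm")
  expect_error(margin_spec(adjacency_mm = -1), ">= 0")
})
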