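test_that("crop window expands the GTV bounding box and clips at edges", {
  dm <- c(128, 128, 64)
  arr <- array(FALSE, dim = dm)
  arr[21:31, 41:51, 11:13] <- TRUE        # bbox i 21..31, j 41..51, k 11..13
  w <- crop_window(mask_from(arr))
  expect_equal(w$i, c(11, 41))
  expect_equal(w$j, c(31, 61))
  expect_equal(w$k, c(9, 15))

  edge <- array(FALSE, dim = dm)
  edge[1:5, 1:5, 1:2] <- TRUE
  we <- crop_window(mask_from(edge))
  expect_equal(we$i[1], 1)
  expect_equal(we$k[1], 1)

  expect_error(crop_window(mask_from(array(FALSE, dim = dm))), "empty")
})

test_that("background voxels are the non-GTV, non-bone window voxels", {
  dm <- c(20, 20, 10)
  vox <- array(30, dim = dm)
  gtv <- array(FALSE, dim = dm)
  gtv[8:12, 8:12, 4:6] <- TRUE
  vol <- scalar_volume(vox, c(1, 1, 1))
  msk <- mask_from(gtv)
  w <- crop_window(msk)
  nwin <- prod(w$i[2] - w$i[1] + 1, w$j[2] - w$j[1] + 1, w$k[2] - w$k[1] + 1)
  bg <- background_voxels(vol, msk, w)
  expect_equal(length(bg), nwin - sum(gtv))

  # insert bone into the window background: those voxels must drop out
  vox2 <- vox
  bone_idx <- which(!gtv)[1:100]
  vox2[bone_idx] <- 1200
  bg2 <- background_voxels(scalar_volume(vox2, c(1, 1, 1)), msk, w)
  expect_equal(length(bg2), length(bg) - sum(bone_idx %in% bg))
  expect_false(any(bone_idx %in% bg2))

  # GTV filling the whole volume leaves no background
  full <- mask_from(array(TRUE, dim = dm))
  expect_error(background_voxels(vol, full, crop_window(full)),
               "degenerate")
})

test_that("contrast and CNR match hand calculations on constructed voxels", {
  dm <- c(10, 10, 6)
  vox <- array(30, dim = dm)
  gtv <- array(FALSE, dim = dm)
  gtv[4:6, 4:6, 3:4] <- TRUE
  vox[gtv] <- 50
  vox[1, 1, 1] <- 28; vox[1, 2, 1] <- 32   # mean stays 30, sd > 0
  m <- compute_visibility_metrics(scalar_volume(vox, c(1, 1, 1)),
                                  mask_from(gtv))
  expect_equal(m$contrast, 20)
  expect_equal(m$x_roi, 50)
  expect_equal(m$x_bkg, 30)
  expect_equal(m$contrast, m$x_roi - m$x_bkg)
  expect_equal(m$cnr, m$contrast / m$sd_bkg)

  # equal means: contrast and CNR both zero (given nonzero background sd)
  vox0 <- array(30, dim = dm)
  vox0[gtv] <- 30
  vox0[1, 1, 1] <- 28; vox0[1, 1, 2] <- 32   # keep sd > 0, mean 30
  m0 <- compute_visibility_metrics(scalar_volume(vox0, c(1, 1, 1)),
                                   mask_from(gtv))
  expect_equal(m0$contrast, 0)
  expect_equal(m0$cnr, 0)
})

test_that("listed-value example: two background voxels, sample sd", {
  # background {28, 32}: mean 30, sample sd sqrt(8); GTV all 40
  dm <- c(5, 5, 5)
  vox <- array(1200, dim = dm)              # bone everywhere else
  gtv <- array(FALSE, dim = dm)
  gtv[3, 3, 3] <- TRUE
  vox[3, 3, 3] <- 40
  vox[1, 1, 1] <- 28
  vox[2, 1, 1] <- 32
  m <- compute_visibility_metrics(scalar_volume(vox, c(1, 1, 1)),
                                  mask_from(gtv))
  expect_equal(m$n_bkg, 2)
  expect_equal(m$x_bkg, 30)
  expect_equal(m$sd_bkg, sqrt((4 + 4) / 1))
  expect_equal(m$contrast, 10)
  expect_equal(m$cnr, 10 / sqrt(8))
})

test_that("bone voxels never influence the metrics", {
  # voxels at or above the bone threshold contribute nothing: the metrics
  # equal a direct computation on the sub-threshold voxels, whatever values
  # (and however many) the bone voxels take
  set.seed(31)
  for (i in 1:20) {
    ph <- small_phantom(delta_hu = runif(1, -40, 40), sigma_hu = 3, seed = i)
    m0 <- compute_visibility_metrics(ph$image, ph$gtv)
    vox <- ph$image$voxels
    w <- m0$window
    in_win <- array(FALSE, dim = dim(vox))
    in_win[w$i[1]:w$i[2], w$j[1]:w$j[2], w$k[1]:w$k[2]] <- TRUE
    hit <- sample(which(in_win & !ph$gtv$voxels), 50)
    vox[hit] <- 1000 + stats::runif(50, 0, 800)
    m1 <- compute_visibility_metrics(
      scalar_volume(vox, ph$image$spacing), ph$gtv)
    # oracle on the raw arrays, applying the crop/GTV/bone rules directly
    roi <- vox[ph$gtv$voxels & vox < 1000]
    bkg <- vox[in_win & !ph$gtv$voxels & vox < 1000]
    expect_equal(m1$x_roi, mean(roi))
    expect_equal(m1$contrast, mean(roi) - mean(bkg))
    expect_equal(m1$sd_bkg, sd(bkg))
    expect_equal(m1$n_bkg, length(bkg))
    # changing the bone voxels to any other >= 1000 values changes nothing
    vox2 <- vox
    vox2[hit] <- 1000 + stats::runif(50, 0, 2000)
    m2 <- compute_visibility_metrics(
      scalar_volume(vox2, ph$image$spacing), ph$gtv)
    expect_identical(m2$contrast, m1$contrast)
    expect_identical(m2$cnr, m1$cnr)
    expect_identical(m2$n_bkg, m1$n_bkg)
  }
})

test_that("contrast is shift-invariant and scales linearly", {
  ph <- small_phantom(delta_hu = 25, sigma_hu = 4, seed = 12)
  m <- compute_visibility_metrics(ph$image, ph$gtv)
  shifted <- scalar_volume(ph$image$voxels + 100, ph$image$spacing)
  ms <- compute_visibility_metrics(shifted, ph$gtv)
  expect_equal(ms$contrast, m$contrast)
  expect_equal(ms$sd_bkg, m$sd_bkg)
  expect_equal(ms$cnr, m$cnr)
  scaled <- scalar_volume(ph$image$voxels * 3, ph$image$spacing)
  mc <- compute_visibility_metrics(scaled, ph$gtv)
  expect_equal(mc$contrast, 3 * m$contrast)
  expect_equal(sign(mc$cnr), sign(m$cnr))
})

test_that("the filter excludes inside the closed band, keeps outside", {
  expect_equal(apply_visibility_filter(40, "contrast"), "keep")
  expect_equal(apply_visibility_filter(0, "contrast"), "exclude")
  expect_equal(apply_visibility_filter(10, "contrast"), "exclude")
  expect_equal(apply_visibility_filter(-10, "contrast"), "exclude")
  expect_equal(apply_visibility_filter(10.01, "contrast"), "keep")
  expect_equal(apply_visibility_filter(-0.5, "cnr"), "exclude")
  expect_equal(apply_visibility_filter(0.1, "cnr"), "exclude")
  expect_equal(apply_visibility_filter(0.11, "cnr"), "keep")
  expect_equal(apply_visibility_filter(-0.51, "cnr"), "keep")
  expect_error(apply_visibility_filter(NA_real_, "cnr"), "undefined")
})

test_that("increasing |contrast| never flips keep to exclude", {
  vals <- seq(0, 60, by = 0.5)
  verdicts <- vapply(vals, apply_visibility_filter, "", mode = "contrast")
  first_keep <- match("keep", verdicts)
  expect_true(all(verdicts[first_keep:length(verdicts)] == "keep"))
  verdicts_neg <- vapply(-vals, apply_visibility_filter, "",
                         mode = "contrast")
  first_keep_n <- match("keep", verdicts_neg)
  expect_true(all(verdicts_neg[first_keep_n:length(verdicts_neg)] == "keep"))
})

test_that("scores validate and the summary table counts filter survivors", {
  expect_error(visibility_score(5), "1..4")
  expect_silent(visibility_score(c(1, 4, NA)))
  rep_df <- data.frame(case_id = letters[1:6],
                       contrast = c(40, -30, 5, 0, 12, -12),
                       cnr = c(2, -2, 0.05, 0, 0.3, -0.6))
  tab <- score_summary_table(rep_df, scores = c(4, 4, 2, 1, 3, 3))
  expect_equal(tab$n, c(2, 2, 1, 1))               # scores 4,3,2,1
  expect_equal(tab$after_contrast, c(2, 2, 0, 0))  # c,d inside the band
  expect_equal(tab$after_cnr, c(2, 2, 0, 0))
})
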