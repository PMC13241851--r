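test_that("Patlak fit recovers exact graphical forms", {
  grid <- seq(0, 60, by = 0.05)
  input <- plasma_input_curve(grid, gamma_variate_input(grid))
  cum <- pracma::cumtrapz(grid, input$values)[, 1]
  mid <- frame_mid_times()
  cp_mid <- approx(grid, input$values, mid)$y
  icp_mid <- approx(grid, cum, mid)$y

  # tissue = Ki * integral(Cp): slope Ki, intercept 0, r2 = 1
  tac <- time_activity_curve(mid, 0.025 * icp_mid)
  est <- patlak_ki(tac, input, t_star = 20)
  expect_equal(est$ki, 0.025, tolerance = 1e-10)
  expect_equal(est$intercept, 0, tolerance = 1e-10)
  expect_equal(est$r2, 1, tolerance = 1e-8)
  expect_gte(est$n_points, 2)

  # pure vascular signal: slope exactly 0, intercept = blood volume
  tac_v <- time_activity_curve(mid, 0.05 * cp_mid)
  est_v <- patlak_ki(tac_v, input, t_star = 20)
  expect_equal(est_v$ki, 0, tolerance = 1e-12)
  expect_equal(est_v$intercept, 0.05, tolerance = 1e-10)

  # common positive rescaling of both curves leaves slope and intercept
  input10 <- plasma_input_curve(grid, 10 * input$values)
  tac10 <- time_activity_curve(mid, 10 * tac$values)
  est10 <- patlak_ki(tac10, input10, t_star = 20)
  expect_equal(est10$ki, est$ki, tolerance = 1e-12)
  expect_equal(est10$intercept, est$intercept, tolerance = 1e-10)

  expect_error(patlak_ki(time_activity_curve(c(1, 2), c(1, 1)), input,
                         t_star = 20), "t_star")
})

test_that("CMRglu scaling by the lumped constant is exact", {
  expect_equal(cmrglu_from_ki(0.013, 5.0, lc = 0.65), 0.1, tolerance = 1e-12)
  expect_equal(cmrglu_from_ki(0, 5.0), 0)
  expect_identical(formals(cmrglu_from_ki)$lc, 0.65)
  expect_error(cmrglu_from_ki(0.01, 5, lc = 0), "lumped")
  expect_error(cmrglu_from_ki(0.01, -1), "glucose")
})

test_that("IDIF selection prunes contamination and matches the subset oracle", {
  mid <- frame_mid_times()
  nt <- length(mid)
  clean <- gamma_variate_input(mid)
  venous <- data.frame(time = c(30, 45, 60 - 5), value = approx(mid, clean,
                       c(30, 45, 55))$y)
  # 6 identical clean voxels + 1 voxel contaminated at late times
  tacs <- matrix(rep(clean, 7), nrow = 7, byrow = TRUE)
  tacs[7, mid > 25] <- tacs[7, mid > 25] * 3
  dyn <- array(0, dim = c(7, 1, 1, nt)); dyn[, 1, 1, ] <- tacs
  sel <- select_idif(dyn, mid, venous, mip_threshold = 0.1, min_voxels = 3)
  expect_equal(attr(sel, "n_retained"), 6L)
  expect_equal(sel$values, clean, tolerance = 1e-10)
  oracle <- oracle_idif_min_sse(tacs, mid, venous, min_voxels = 3)
  expect_equal(attr(sel, "residual_ss"), oracle, tolerance = 1e-10)

  # pruning disabled when min_voxels equals the candidate count
  sel_all <- select_idif(dyn, mid, venous, mip_threshold = 0.1,
                         min_voxels = 7)
  expect_equal(sel_all$values, colMeans(tacs), tolerance = 1e-12)

  expect_error(select_idif(dyn, mid, venous[1:2, ], 0.1), "venous")
  bad <- venous; bad$time[1] <- 200
  expect_error(select_idif(dyn, mid, bad, 0.1), "window")
})

test_that("ROI aggregation returns per-label means and flags absent labels", {
  arr <- array(0L, dim = c(4, 3, 2))
  arr[1:2, 1, 1] <- 1L; arr[3:4, 2, 2] <- 2L
  lv <- label_volume(arr, c(left = 1L, right = 2L, ghost = 9L))
  vol <- array(seq_len(24), dim = c(4, 3, 2))
  out <- aggregate_roi(vol, lv)
  expect_equal(out[["left"]], mean(vol[1:2, 1, 1]))
  expect_equal(out[["right"]], mean(vol[3:4, 2, 2]))
  expect_true(is.na(out[["ghost"]]))

  # constant volume and affine commutation
  expect_true(all(aggregate_roi(array(7, dim(arr)), lv)[1:2] == 7))
  out_affine <- aggregate_roi(3 * vol + 2, lv)
  expect_equal(out_affine[1:2], 3 * out[1:2] + 2, tolerance = 1e-12)

  expect_error(aggregate_roi(array(0, c(2, 2, 2)), lv), "grids")
})

test_that("putamen subdivision matches the exhaustive 1-D k-means oracle", {
  # uniform AP indices 0..29 split into equal thirds
  arr <- array(0L, dim = c(1, 30, 1))
  arr[1, , 1] <- 5L
  lv <- label_volume(arr, c(putamen = 5L), ap_axis = 2L,
                     anterior_high = FALSE)
  sub <- subdivide_putamen(lv, "putamen")
  ap_of <- function(name) which(sub$array[1, , 1] == sub$labels[[name]]) - 1L
  expect_equal(ap_of("putamen_anterior"), 0:9)
  expect_equal(ap_of("putamen_middle"), 10:19)
  expect_equal(ap_of("putamen_posterior"), 20:29)
  expect_false("putamen" %in% names(sub$labels))

  # random index distributions (with ties): oracle-equal WSS, contiguous
  # non-empty clusters ordered along the AP axis
  for (seed in 1:5) {
    idx <- withr::with_seed(seed, sample.int(40, 25, replace = TRUE))
    arr2 <- array(0L, dim = c(25, 50, 1))
    for (i in seq_along(idx)) arr2[i, idx[i], 1] <- 3L
    lv2 <- label_volume(arr2, c(put = 3L), ap_axis = 2L, anterior_high = FALSE)
    sub2 <- subdivide_putamen(lv2, "put")
    assign_ap <- lapply(c("put_anterior", "put_middle", "put_posterior"),
                        function(nm) {
                          which(sub2$array == sub2$labels[[nm]],
                                arr.ind = TRUE)[, 2]
                        })
    wss <- sum(vapply(assign_ap,
                      function(g) sum((g - mean(g))^2), numeric(1)))
    expect_equal(wss, oracle_kmeans3_1d(idx)$wss, tolerance = 1e-9)
    expect_true(all(vapply(assign_ap, length, integer(1)) > 0))
    rng <- t(vapply(assign_ap, range, numeric(2)))
    expect_true(rng[1, 2] <= rng[2, 1] && rng[2, 2] <= rng[3, 1])
  }

  # exactly three distinct index values -> one cluster per value
  arr3 <- array(0L, dim = c(1, 10, 1))
  arr3[1, c(2, 5, 9), 1] <- 4L
  lv3 <- label_volume(arr3, c(p = 4L), ap_axis = 2L, anterior_high = FALSE)
  sub3 <- subdivide_putamen(lv3, "p")
  expect_equal(which(sub3$array[1, , 1] == sub3$labels[["p_anterior"]]), 2L)
  expect_equal(which(sub3$array[1, , 1] == sub3$labels[["p_middle"]]), 5L)
  expect_equal(which(sub3$array[1, , 1] == sub3$labels[["p_posterior"]]), 9L)

  arr4 <- array(0L, dim = c(1, 10, 1)); arr4[1, c(2, 5), 1] <- 4L
  lv4 <- label_volume(arr4, c(p = 4L), ap_axis = 2L)
  expect_error(subdivide_putamen(lv4, "p"), "distinct")
})
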