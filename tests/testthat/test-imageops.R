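# Rolling-ball background, registration, ROI traces, CV line scans, line
# profiles and 2D droplet colocalization.

test_that("rolling-ball background subtraction matches a brute-force opening oracle", {
  # constant image -> all zero
  expect_true(all(rolling_ball_background(matrix(9, 30, 30), 5) == 0))
  # a small bright disk on a flat background survives nearly intact
  img <- matrix(10, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    if ((i - 20)^2 + (j - 20)^2 <= 3^2) img[i, j] <- 110
  }
  out <- rolling_ball_background(img, 8)
  oracle_bg <- oracle_disc_opening(img, 8)
  expect_equal(out, pmax(img - oracle_bg, 0), tolerance = 1e-9)
  expect_gt(out[20, 20], 0.95 * 100)
  # a linear ramp is removed to < 2% residual slope
  ramp <- outer(rep(1, 60), seq(0, 59)) * 2
  spot <- ramp
  spot[30, 30] <- spot[30, 30] + 300
  res <- rolling_ball_background(spot, 10)
  cols <- 15:45
  slope <- coef(lm(colMeans(res)[cols] ~ cols))[2]
  expect_lt(abs(slope), 0.02 * 2)
  expect_warning(rolling_ball_background(matrix(runif(100), 10, 10), 50),
                 "global minimum")
})

test_that("translation registration recovers integer shifts exactly and subpixel shifts closely", {
  base <- matrix(0, 64, 64)
  for (ctr in list(c(20, 25), c(40, 35), c(30, 50))) {
    base <- base + oracle_spot_frame(64, 64, ctr[2], ctr[1], 2, 2, 1000)
  }
  shift_int <- function(m, dy, dx) {
    out <- matrix(0, nrow(m), ncol(m))
    src_r <- seq_len(nrow(m)) - dy
    src_c <- seq_len(ncol(m)) - dx
    ok_r <- src_r >= 1 & src_r <= nrow(m)
    ok_c <- src_c >= 1 & src_c <= ncol(m)
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out
  }
  stack <- array(c(base, shift_int(base, -2, 3)), dim = c(64, 64, 2))
  reg <- register_timelapse(stack)
  expect_equal(reg$shifts$dy_px[2], -2, tolerance = 1e-6)
  expect_equal(reg$shifts$dx_px[2], 3, tolerance = 1e-6)
  expect_lt(max(abs(reg$stack[5:60, 5:60, 2] - base[5:60, 5:60])), 1e-6)

  # identical frames: zero shift
  reg0 <- register_timelapse(array(rep(base, 2), dim = c(64, 64, 2)))
  expect_true(all(reg0$shifts$dx_px == 0))

  # half-pixel shift recovered within a quarter pixel
  half <- matrix(0, 64, 64)
  for (ctr in list(c(20, 25), c(40, 35), c(30, 50))) {
    half <- half + oracle_spot_frame(64, 64, ctr[2] + 0.5, ctr[1], 2, 2, 1000)
  }
  regh <- register_timelapse(array(c(base, half), dim = c(64, 64, 2)))
  expect_lt(abs(regh$shifts$dx_px[2] - 0.5), 0.25)
  expect_warning(register_timelapse(array(1, dim = c(16, 16, 2))),
                 "Featureless")
  expect_error(register_timelapse(array(1, dim = c(16, 16, 1))),
               "at least 2 frames")
})

test_that("ROI disk traces equal the mean over an enumerated pixel disk", {
  stack <- array(3.5, dim = c(40, 40, 6))
  centers <- tibble::tibble(roi = "r1", x_px = 20, y_px = 20)
  tr <- extract_roi_traces(stack, centers, diameter_um = 1.08,
                          pixel_size_nm = 200)
  expect_true(all(tr$f == 3.5))
  expect_equal(tr$t, seq(0, 25, by = 5))

  # disk membership matches a brute-force distance predicate
  withr::with_seed(4, {
    img <- matrix(runif(1600), 40, 40)
  })
  tr2 <- extract_roi_traces(array(img, dim = c(40, 40, 1)), centers,
                            diameter_um = 1.08, pixel_size_nm = 200)
  r_px <- 1.08 * 1000 / 2 / 200
  sel <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    sel[i, j] <- ((j - 0.5) - 20)^2 + ((i - 0.5) - 20)^2 <= r_px^2
  }
  expect_equal(tr2$f, mean(img[sel]))

  # a punctum-centered ROI is brighter than a background ROI
  p <- img + oracle_spot_frame(40, 40, 10, 10, 1.5, 1.5, 500)
  tr3 <- extract_roi_traces(array(p, dim = c(40, 40, 1)),
                            tibble::tibble(roi = c("punctum", "bg"),
                                           x_px = c(10, 30), y_px = c(10, 30)),
                            pixel_size_nm = 200)
  expect_gt(tr3$f[tr3$roi == "punctum"], tr3$f[tr3$roi == "bg"])
  expect_error(
    extract_roi_traces(stack, tibble::tibble(roi = "edge", x_px = 1, y_px = 20),
                       pixel_size_nm = 200),
    "clipped")
})

test_that("CV along a line scan matches direct enumeration and is scale invariant", {
  # constant band
  const <- matrix(4, 30, 30)
  line <- tibble::tibble(x_px = c(5, 25), y_px = c(15, 15))
  expect_identical(cv_along_line(const, line)$cv, 0)
  # alternating {0, 2} columns in equal proportion: mean 1, sd ~1, CV ~1
  alt <- matrix(rep(c(0, 2), length.out = 30 * 30), 30, 30, byrow = TRUE)
  line20 <- tibble::tibble(x_px = c(5, 24.5), y_px = c(15, 15))
  got <- cv_along_line(alt, line20, width = 5)
  expect_equal(got$mean, 1)
  expect_equal(got$cv, sd(rep(c(0, 2), 50)) / 1, tolerance = 0.02)
  # positive scaling leaves CV unchanged
  expect_equal(cv_along_line(10 * alt, line20, width = 5)$cv, got$cv,
               tolerance = 1e-12)
  expect_error(cv_along_line(matrix(0, 30, 30), line), "Zero mean")
})

test_that("redistributing punctate intensity to uniform strictly lowers the CV", {
  # synthetic axon: bright puncta on a dim line
  axon <- matrix(1, 20, 120)
  for (cx in seq(15, 105, by = 15)) {
    axon <- axon + oracle_spot_frame(20, 120, cx, 10, 1.5, 1.5, 400)
  }
  line <- tibble::tibble(x_px = c(5, 115), y_px = c(10, 10))
  cv_punctate <- cv_along_line(axon, line, width = 5)$cv
  uniform <- matrix(mean(axon), 20, 120)
  # conserve the total intensity exactly
  expect_equal(sum(uniform), sum(axon))
  cv_uniform <- cv_along_line(uniform, line, width = 5)$cv
  expect_lt(cv_uniform, cv_punctate)
  expect_identical(cv_uniform, 0)
})

test_that("line profiles are normalized to their maximum with nearest-pixel sampling", {
  withr::with_seed(9, {
    img <- matrix(runif(900, 1, 5), 30, 30)
  })
  line <- tibble::tibble(x_px = c(4.2, 24.2), y_px = c(10.7, 10.7))
  prof <- line_scan_profile(img, line)
  expect_identical(max(prof$intensity_norm), 1)
  # oracle: nearest-pixel lookup at unit steps
  want <- vapply(seq(0, 20, by = 1), function(s) {
    img[floor(10.7) + 1, floor(4.2 + s) + 1]
  }, numeric(1))
  expect_equal(prof$intensity, want)
  # constant line maps to all ones
  flat <- line_scan_profile(matrix(2, 30, 30), line)
  expect_true(all(flat$intensity_norm == 1))
  expect_error(line_scan_profile(matrix(0, 30, 30), line), "All-zero")
})

test_that("2D droplet colocalization reproduces pixel-count Manders", {
  mk_droplets <- function(centers) {
    img <- matrix(0, 80, 80)
    for (ctr in centers) {
      img <- img + oracle_spot_frame(80, 80, ctr[1], ctr[2], 3, 3, 4000)
    }
    img + 5
  }
  a <- mk_droplets(list(c(20, 20), c(60, 30), c(30, 60)))
  res_same <- droplet_colocalization_2d(a, a, rolling_ball_radius = 15)
  expect_identical(res_same$metrics$manders_a_in_b, 1)
  expect_identical(res_same$metrics$manders_b_in_a, 1)

  b <- mk_droplets(list(c(20, 20), c(60, 30), c(65, 65)))
  res <- droplet_colocalization_2d(a, b, rolling_ball_radius = 15)
  # the reported coefficients equal brute-force pixel counting on the masks
  ov <- sum(res$mask_a & res$mask_b)
  expect_identical(res$metrics$manders_a_in_b, ov / sum(res$mask_a))
  expect_identical(res$metrics$manders_b_in_a, ov / sum(res$mask_b))
  expect_gt(res$metrics$manders_a_in_b, 0.5)
  expect_lt(res$metrics$manders_a_in_b, 0.9)

  d <- mk_droplets(list(c(60, 60)))
  c1 <- mk_droplets(list(c(20, 20)))
  res0 <- droplet_colocalization_2d(c1, d, rolling_ball_radius = 15)
  expect_identical(res0$metrics$manders_a_in_b, 0)
  expect_error(droplet_colocalization_2d(matrix(1, 10, 10), matrix(1, 10, 10)),
               "Constant channel")
})
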