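# Spot detection, 2D Gaussian fitting, z calibration, drift correction and
# quality filtering.

test_that("frame smoothing matches a dense convolution oracle", {
  withr::with_seed(3, {
    frame <- matrix(runif(20 * 24), 20, 24)
  })
  expect_lt(max(abs(preprocess_frame(frame, radius = 1) -
                      oracle_gaussian_conv2d(frame, 0.5))), 1e-9)
  # constant frame is preserved; radius 0 is the identity
  const <- matrix(3.7, 16, 16)
  expect_equal(preprocess_frame(const, 1), const)
  expect_identical(preprocess_frame(frame, 0), frame)
  # unit impulse keeps unit mass (kernel normalization)
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  expect_equal(sum(preprocess_frame(imp, 1)), 1, tolerance = 1e-12)
})

test_that("candidate detection finds isolated maxima and nothing on flat frames", {
  expect_identical(nrow(detect_candidates(matrix(5, 20, 20))), 0L)
  f1 <- oracle_spot_frame(31, 31, 10.5, 12.5, 1, 1, 2000, offset = 3)
  c1 <- detect_candidates(preprocess_frame(f1))
  expect_identical(nrow(c1), 1L)
  expect_identical(c(c1$row, c1$col), c(13L, 11L))
  # two spots 20 px apart match the exhaustive local-maximum oracle
  f2 <- oracle_spot_frame(41, 41, 10.5, 12.5, 1, 1, 2000, offset = 3) +
    oracle_spot_frame(41, 41, 30.5, 12.5, 1, 1, 2000)
  sm <- preprocess_frame(f2)
  c2 <- detect_candidates(sm)
  thr <- mean(sm) + 4 * sd(sm)
  oracle <- oracle_local_maxima(sm, thr)
  expect_identical(nrow(c2), 2L)
  expect_setequal(paste(c2$row, c2$col),
                  paste(oracle[, 1], oracle[, 2]))
})

test_that("noiseless spot fits recover the generating parameters exactly", {
  truth <- list(x = 10.37, y = 9.81, sx = 1.13, sy = 0.94,
                photons = 2500, offset = 12)
  frame <- oracle_spot_frame(21, 21, truth$x, truth$y, truth$sx, truth$sy,
                             truth$photons, truth$offset)
  fit <- fit_spot_2d(frame, 10, 11, pixel_size = 200)
  expect_true(fit$accepted)
  expect_lt(abs(fit$x_nm / 200 - truth$x) / truth$x, 1e-6)
  expect_lt(abs(fit$y_nm / 200 - truth$y) / truth$y, 1e-6)
  expect_lt(abs(fit$wx_nm / 200 - truth$sx) / truth$sx, 1e-6)
  expect_lt(abs(fit$wy_nm / 200 - truth$sy) / truth$sy, 1e-6)
  expect_lt(abs(fit$amplitude - truth$photons) / truth$photons, 1e-6)
  # flat window is rejected
  flat <- fit_spot_2d(matrix(9, 21, 21), 10, 10)
  expect_false(flat$accepted)
  # clipped window is skipped
  expect_null(fit_spot_2d(frame, 2, 2))
})

test_that("Poisson-noise localization error matches an independent optimizer", {
  om <- optics_model()
  px <- om$pixel_size
  s_px <- om$psf_sigma_focus / px
  n_rep <- 200
  res <- withr::with_seed(7, {
    t(vapply(seq_len(n_rep), function(i) {
      x <- 10 + runif(1) - 0.5
      mu <- oracle_spot_frame(21, 21, x, 10.5, s_px, s_px,
                              om$photons_per_emitter, om$background_rate)
      frame <- matrix(rpois(length(mu), mu), 21, 21)
      fit <- fit_spot_2d(frame, 10, 10, pixel_size = px)
      # 7 px window rows/cols 7:13; window coordinates are offset by 6
      oracle_x <- oracle_fit_spot_x(frame[7:13, 7:13], x - 6, 4.5, s_px) + 6
      c(impl = fit$x_nm / px - x, oracle = oracle_x - x)
    }, numeric(2)))
  })
  rmse <- function(e) sqrt(mean(e^2))
  # same draws, independent optimizer: the implementation may not be more
  # than 10% worse
  expect_lt(rmse(res[, "impl"]), 1.1 * rmse(res[, "oracle"]))
  expect_lt(abs(mean(res[, "impl"])) * px, 2)
  expect_lt(rmse(res[, "impl"]) * px, 15)
})

test_that("astigmatism calibration interpolates nodes exactly and inverts z", {
  om <- optics_model()
  tbl <- simulate_calibration_stack(om, z_range = 400, z_step = 25)
  cal <- fit_astigmatism_calibration(tbl)
  # node reproduction and focus symmetry
  expect_equal(assign_z(tbl$wx, tbl$wy, cal), tbl$z)
  expect_identical(assign_z(250, 250, cal), 0)
  # mid-node queries on the model curve stay within half a step
  zq <- seq(-300, 300, by = 12.5)
  w <- psf_widths(om, zq)
  expect_lt(max(abs(assign_z(w$wx, w$wy, cal) - zq)), 25 / 2)
  # noiseless inversion over +/-300 nm on a dense calibration
  cal10 <- fit_astigmatism_calibration(
    simulate_calibration_stack(om, z_range = 400, z_step = 10))
  w2 <- psf_widths(om, seq(-300, 300, by = 10))
  expect_lt(max(abs(assign_z(w2$wx, w2$wy, cal10) - seq(-300, 300, by = 10))), 1)
  # out-of-range width differences are excluded
  expect_true(is.na(assign_z(1000, 100, cal)))
  # non-monotone width difference is rejected
  bad <- tbl
  bad$wx[10] <- bad$wx[12]
  bad$wy[10] <- bad$wy[12]
  expect_error(fit_astigmatism_calibration(bad), "not strictly monotone")
})

make_drift_movie <- function(rate, n_frames, fid, seed = 2, noise = "poisson") {
  gt <- make_small_truth()
  om <- optics_model(noise_model = noise)
  acq <- acquisition_spec(
    n_frames = n_frames, frame_size = c(48, 48), emitters_per_frame = 0,
    drift = if (!is.null(rate)) linear_drift(rate),
    fiducials = fid, seed = seed)
  sim <- simulate_blinking_movie(gt, om, acq)
  cal <- fit_astigmatism_calibration(simulate_calibration_stack(om))
  localize_stack(sim$stack, cal)
}

test_that("drift estimation is zero for stationary fiducials and averages over beads", {
  fid1 <- tibble::tibble(x_nm = 3000, y_nm = 3000, photons = 30000)
  locs <- make_drift_movie(NULL, 120, fid1, noise = "none")
  tr <- estimate_drift(locs, fid1, n_frames = 120)
  expect_lt(max(abs(c(tr$dx, tr$dy))), 1e-6)

  # two beads with shared drift + independent shot noise: averaging reduces
  # the raw (unsmoothed) trace variance
  fid2 <- tibble::tibble(x_nm = c(3000, 6500), y_nm = c(3000, 6500),
                         photons = 30000)
  locs2 <- make_drift_movie(c(0.5, 0, 0), 150, fid2)
  tr_pair <- estimate_drift(locs2, fid2, n_frames = 150, smooth_window = 1)
  tr_one <- estimate_drift(locs2, fid2[1, ], n_frames = 150, smooth_window = 1)
  lin <- function(v) v - seq_along(v) * 0.5 + 0.5
  expect_lt(var(lin(tr_pair$dx)), var(lin(tr_one$dx)))
  expect_error(
    estimate_drift(locs2, tibble::tibble(x_nm = 100, y_nm = 100), 150),
    "No fiducial")
})

test_that("drift correction subtracts the trace and zero traces are no-ops", {
  fid <- tibble::tibble(x_nm = 3000, y_nm = 3000, photons = 30000)
  locs <- make_drift_movie(c(0.5, -0.3, 0), 150, fid)
  zero <- tibble::tibble(frame = 1:150, dx = 0, dy = 0, dz = 0)
  expect_equal(apply_drift_correction(locs, zero)$x_nm, locs$x_nm)
  tr <- estimate_drift(locs, fid, n_frames = 150)
  corr <- apply_drift_correction(locs, tr)
  # corrected fiducial scatter must not exceed the uncorrected scatter
  expect_lte(sd(corr$x_nm), sd(locs$x_nm))
  expect_error(apply_drift_correction(locs, tr[1:10, ]), "cover every frame")
})

test_that("quality filtering matches a brute-force predicate oracle", {
  withr::with_seed(11, {
    tbl <- tibble::tibble(
      frame = 1:200, channel = "A",
      x_nm = runif(200, 0, 5000), y_nm = runif(200, 0, 5000),
      z_nm = runif(200, -300, 300),
      wx_nm = runif(200, 80, 500), wy_nm = runif(200, 80, 500),
      amplitude = runif(200, 50, 5000), offset = 10,
      residual = runif(200, 0, 0.2), accepted = runif(200) > 0.1)
  })
  out <- filter_localizations(tbl, width_range = c(100, 400),
                              amplitude_min = 500, amplitude_max = 4000,
                              residual_max = 0.1, quiet = TRUE)
  keep <- with(tbl, accepted & wx_nm >= 100 & wx_nm <= 400 &
                 wy_nm >= 100 & wy_nm <= 400 &
                 amplitude >= 500 & amplitude <= 4000 & residual <= 0.1)
  expect_identical(out$frame, tbl$frame[keep])
  # all-pass bounds keep everything accepted
  allp <- filter_localizations(tbl, quiet = TRUE)
  expect_identical(nrow(allp), sum(tbl$accepted))
  expect_warning(
    filter_localizations(tbl, amplitude_min = 1e9, quiet = TRUE),
    "All localizations removed")
  expect_error(filter_localizations(tbl, width_range = c(400, 100)),
               "inverted")
})
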