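# Synthetic-data generator: geometry truth, blinking movies, calibration
# stacks, kinetics and FRAP traces.

test_that("ground-truth geometry gives exact voxel-count truth", {
  # identical concentric spheres
  gt <- generate_ground_truth_synapse(synapse_geometry(
    c(0, 0, 0), 150, c(0, 0, 0), 150))
  expect_identical(gt$truth$overlap_a_in_b, 1)
  expect_identical(gt$truth$overlap_b_in_a, 1)
  expect_identical(gt$truth$volume_ratio_a_over_b, 1)
  expect_identical(gt$truth$com_distance_nm, 0)

  # small sphere concentric inside a big one: full containment, ~8x volume
  gt2 <- generate_ground_truth_synapse(synapse_geometry(
    c(0, 0, 0), 100, c(0, 0, 0), 200))
  expect_identical(gt2$truth$overlap_a_in_b, 1)
  expect_lt(abs(gt2$truth$voxels_b / gt2$truth$voxels_a - 8), 8 * 0.02)

  # lateral offset is reproduced exactly by symmetry of the voxelization
  gt3 <- make_small_truth(radius = 100, offset = 50)
  expect_equal(gt3$truth$com_distance_nm, 50, tolerance = 1e-9)
})

test_that("geometry rejects clusters escaping the bounding box", {
  geom <- synapse_geometry(c(0, 0, 0), 150, c(50, 0, 0), 150,
                           bounds = list(x = c(-100, 100), y = c(-200, 200),
                                         z = c(-200, 200)))
  expect_error(generate_ground_truth_synapse(geom), "beyond the bounding box")
  expect_error(synapse_geometry(c(0, 0, 0), 20, c(0, 0, 0), 150),
               "at least 3 voxel edges")
})

test_that("geometry_for_overlap hits the target overlap on the voxel grid", {
  for (f in c(0.2, 0.5, 0.8)) {
    gt <- geometry_for_overlap(f, radius_a = 110)
    expect_lt(abs(gt$truth$overlap_a_in_b - f), 0.011)
    expect_equal(gt$truth$com_distance_nm, 50, tolerance = 0.5)
  }
})

test_that("noise-free movie with no emitters is exactly the background", {
  gt <- make_small_truth()
  om <- optics_model(noise_model = "none", background_rate = 7)
  acq <- acquisition_spec(n_frames = 4, frame_size = c(32, 32),
                          emitters_per_frame = 0, seed = 1)
  sim <- simulate_blinking_movie(gt, om, acq)
  expect_true(all(sim$stack$pixels == 7))
  expect_identical(nrow(sim$truth_locs), 0L)
})

test_that("a single in-focus emitter lands on the brightest pixel with wx == wy", {
  om <- optics_model(noise_model = "none", background_rate = 0)
  px <- om$pixel_size
  frame <- matrix(0, 32, 32)
  # place one emitter at a known off-center subpixel position, z = 0
  x <- 15.3 * px; y <- 18.7 * px
  w <- psf_widths(om, 0)
  expect_equal(w$wx, w$wy)
  frame <- frame + oracle_spot_frame(32, 32, x / px, y / px, w$wx / px,
                                     w$wy / px, om$photons_per_emitter)
  peak <- which(frame == max(frame), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak["col"]), floor(x / px) + 1)
  expect_equal(unname(peak["row"]), floor(y / px) + 1)
  fit <- fit_spot_2d(frame, peak["row"], peak["col"], pixel_size = px)
  expect_true(fit$accepted)
  expect_lt(abs(fit$wx_nm - fit$wy_nm), 1e-3)
})

test_that("photon flux is conserved in noise-free frames", {
  gt <- make_small_truth()
  om <- optics_model(noise_model = "none", background_rate = 5)
  acq <- acquisition_spec(n_frames = 10, frame_size = c(64, 64),
                          emitters_per_frame = 2, seed = 42)
  sim <- simulate_blinking_movie(gt, om, acq)
  for (f in seq_len(10)) {
    n_em <- sum(sim$truth_locs$frame == f)
    total <- sum(sim$stack$pixels[, , f]) - 5 * 64 * 64
    expect_equal(total, n_em * om$photons_per_emitter,
                 tolerance = 0.01 * max(1, n_em * om$photons_per_emitter))
  }
})

test_that("emitters obey the channel schedule and stay inside their masks", {
  gt <- geometry_for_overlap(0.2, radius_a = 100)
  om <- optics_model()
  acq <- acquisition_spec(n_frames = 40, frame_size = c(64, 64),
                          emitters_per_frame = 3, seed = 5)
  sim <- simulate_blinking_movie(gt, om, acq)
  tl <- sim$truth_locs
  expect_true(all(tl$channel == acq$channel_schedule[tl$frame]))
  # map each truth position back to its voxel and check mask membership
  for (ch in c("A", "B")) {
    mask <- if (ch == "A") gt$mask_a else gt$mask_b
    sub <- tl[tl$channel == ch, ]
    ix <- floor((sub$x_nm - sim$offset_nm[1] - gt$origin[1]) / gt$voxel_edge) + 1
    iy <- floor((sub$y_nm - sim$offset_nm[2] - gt$origin[2]) / gt$voxel_edge) + 1
    iz <- floor((sub$z_nm - gt$origin[3]) / gt$voxel_edge) + 1
    expect_true(all(mask[cbind(ix, iy, iz)]))
  }
})

test_that("a drifting fiducial's intensity centroid tracks the injected drift", {
  gt <- make_small_truth()
  om <- optics_model(noise_model = "none", background_rate = 0)
  acq <- acquisition_spec(
    n_frames = 50, frame_size = c(32, 32), emitters_per_frame = 0,
    drift = linear_drift(c(1, 0, 0)),
    fiducials = tibble::tibble(x_nm = 3000, y_nm = 3000, photons = 20000),
    seed = 1)
  sim <- simulate_blinking_movie(gt, om, acq)
  centroid_x <- function(fr) {
    cols <- (seq_len(ncol(fr)) - 0.5) * om$pixel_size
    sum(colSums(fr) * cols) / sum(fr)
  }
  c1 <- centroid_x(sim$stack$pixels[, , 1])
  c50 <- centroid_x(sim$stack$pixels[, , 50])
  expect_equal(c50 - c1, 49, tolerance = 0.2)
})

test_that("movies are bit-reproducible from (spec, seed)", {
  gt <- make_small_truth()
  om <- optics_model()
  acq <- acquisition_spec(n_frames = 6, frame_size = c(32, 32),
                          emitters_per_frame = 2, seed = 9)
  s1 <- suppressWarnings(simulate_blinking_movie(gt, om, acq))
  s2 <- suppressWarnings(simulate_blinking_movie(gt, om, acq))
  expect_identical(s1$stack$pixels, s2$stack$pixels)
  expect_identical(s1$truth_locs, s2$truth_locs)
  acq2 <- acquisition_spec(n_frames = 6, frame_size = c(32, 32),
                           emitters_per_frame = 2, seed = 10)
  s3 <- suppressWarnings(simulate_blinking_movie(gt, om, acq2))
  expect_false(identical(s1$stack$pixels, s3$stack$pixels))
})

test_that("calibration stacks evaluate the width curves on an ordered grid", {
  om <- optics_model()
  cal <- simulate_calibration_stack(om, z_range = 400, z_step = 10)
  expect_identical(nrow(cal), 81L)
  expect_equal(cal$wx[cal$z == 0], cal$wy[cal$z == 0])
  d <- cal$wx - cal$wy
  expect_true(all(diff(d) > 0))
  expect_error(simulate_calibration_stack(om, z_range = 500),
               "exceeds the validity range")
})

test_that("puncta time series follow the piecewise monoexponential model", {
  kin <- kinetics_truth(amplitude = 0.36, tau_dispersion = 23.5, noise_sd = 0)
  tr <- simulate_puncta_timeseries(kin, n_puncta = 1, seed = 1)
  f15 <- tr$f[tr$t == 15]
  f75 <- tr$f[tr$t == 75]
  expect_equal((f75 - f15) / kin$f0, -0.36 * (1 - exp(-60 / 23.5)),
               tolerance = 1e-12)
  # zero amplitude (mobile fraction 0) leaves the trace flat
  flat <- simulate_puncta_timeseries(kinetics_truth(amplitude = 0), 1, seed = 1)
  expect_true(all(abs(flat$f - flat$f[1]) < 1e-12))
  # recovery reaches within 5% of its plateau by three time constants
  kin2 <- kinetics_truth(amplitude = 0.36, tau_dispersion = 23.5,
                         tau_recovery = 60, trace_end = 320)
  tr2 <- simulate_puncta_timeseries(kin2, 1, seed = 1)
  drop_end <- 0.36 * (1 - exp(-60 / 23.5))
  plateau <- 1 - drop_end + kin2$recovery_fraction * drop_end
  at3tau <- tr2$f[tr2$t == 75 + 3 * 60]
  expect_lt(abs(at3tau - plateau), 0.05 * plateau)
  expect_error(kinetics_truth(noise_sd = -0.1), ">= 0")
})

test_that("FRAP traces have the stated plateau structure", {
  full <- simulate_frap_trace(frap_truth(mobile_fraction = 1, tau_recovery = 10,
                                         trace_end = 300))
  expect_equal(full$f[nrow(full)], 1, tolerance = 1e-6)
  half <- simulate_frap_trace(frap_truth(mobile_fraction = 0.5,
                                         bleach_depth = 0, tau_recovery = 10,
                                         trace_end = 300))
  expect_equal(half$f[nrow(half)], 0.5, tolerance = 1e-6)
  expect_error(frap_truth(bleach_time = 0), "must not precede")
})
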