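test_that("beer_lambert_od is the extinction x path x concentration product", {
  expect_identical(beer_lambert_od(1, 1, 1), 1)
  expect_identical(beer_lambert_od(2, 0.1, 0), 0)
  od <- beer_lambert_od(5.3, 0.1, 0.4)
  expect_equal(od, 0.212)
  expect_equal(10^-od, 0.6137620, tolerance = 1e-6)
  expect_error(beer_lambert_od(-1, 1, 1), ">= 0")
  # vectorization over a concentration trace
  expect_equal(beer_lambert_od(5.3, 0.1, c(0, 0.2, 0.4)),
               c(0, 0.106, 0.212))
})

test_that("delta_od_series is log10(I0/I) anchored at the first sample", {
  const <- delta_od_series(rep(123.4, 50))
  expect_true(all(const$delta_od == 0))
  x <- rep(100, 10); x[4] <- 50
  expect_equal(delta_od_series(x)$delta_od[4], log10(2))
  # an intensity decrease (more hemoglobin) raises delta OD
  expect_gt(delta_od_series(c(100, 80))$delta_od[2], 0)
  expect_error(delta_od_series(c(100, 0, 50)), "index 2")
})

test_that("noise-free CWS forward model inverts to eps*L*(C(t) - C(0))", {
  cfg <- simulation_config(
    seed = 5, cws_noise_sigma = 0, cws_jitter = 0, cws_duration = 60,
    vasomotion = vasomotion_params(TRUE, period = 20, modulation_depth = 0.05))
  out <- generate_cws_recording(cfg)
  rec <- out$recording
  i500 <- rec$intensities[rec$wavelengths == 500, ]
  ods <- delta_od_series(i500, rec$timestamps, source = "CWS")
  eps500 <- 5.3  # isosbestic extinction at 500 nm in the packaged table
  expected <- eps500 * cfg$path_length *
    (out$truth$concentration - out$truth$concentration[1])
  expect_equal(ods$delta_od, expected, tolerance = 1e-9)
})

test_that("mean_frame_intensity averages all pixels per frame", {
  expect_equal(mean_frame_intensity(uniform_seq(7)), rep(7, 15))
  stack <- array(0, c(10, 10, 3)); stack[1:5, , ] <- 100
  seq <- frame_sequence(list(`450` = stack), 0:2 / 21, 0.6466)
  expect_equal(mean_frame_intensity(seq), rep(50, 3))
  expect_error(mean_frame_intensity(uniform_seq(7), 438), "438")
  # saturated pixels are excluded with a message
  stack[1, 1, ] <- 4095
  seq <- frame_sequence(list(`450` = stack), 0:2 / 21, 0.6466)
  expect_message(mfi <- mean_frame_intensity(seq), "saturated")
  expect_equal(mfi, rep(mean(stack[, , 1][-1]), 3))
})

test_that("MFI modulation depth matches the injected hemoglobin modulation", {
  vaso <- vasomotion_params(TRUE, period = 10, modulation_depth = 0.05)
  cfg <- quick_cfg(list(program_stopped(quick_centerline())),
                   duration = 20, seed = 31, vasomotion = vaso)
  out <- generate_capillary_video(cfg)
  ods <- delta_od_series(mean_frame_intensity(out$sequence, 450),
                         out$sequence$timestamps)
  measured <- diff(range(ods$delta_od)) / 2
  injected <- cfg$tissue_od * vaso$modulation_depth
  expect_lt(abs(measured - injected) / injected, 0.05)
})

test_that("rbc_so2 maps the OD ratio affinely between calibration endpoints", {
  cal <- calibration_constants(ratio_oxy = 1.2, ratio_deoxy = 0.6)
  expect_equal(rbc_so2(1.2, 1, cal), 1)
  expect_equal(rbc_so2(0.6, 1, cal), 0)
  expect_equal(rbc_so2(0.9, 1, cal), 0.5)
  # saturates outside the endpoints
  expect_equal(rbc_so2(1.5, 1, cal), 1)
  expect_equal(rbc_so2(0.3, 1, cal), 0)
  expect_error(rbc_so2(0.5, 0, cal), "od_450")
  # affine in R between the endpoints
  r <- seq(0.6, 1.2, by = 0.1)
  so2 <- rbc_so2(r, rep(1, length(r)), cal)
  expect_equal(diff(so2), rep(diff(so2)[1], length(r) - 1), tolerance = 1e-12)
})

test_that("isosbestic_average is the unweighted mean of the six band OD series", {
  tt <- 0:9 / 10.5
  one_band <- c(0, 0.1, 0.05, 0.2, 0, 0.1, 0.3, 0.2, 0.1, 0)
  rec <- iso_recording(rep(list(one_band), 6), tt)
  expect_equal(isosbestic_average(rec)$delta_od, one_band, tolerance = 1e-12)
  # distinct instantaneous band values average arithmetically
  vals <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  ods <- lapply(vals, function(v) c(0, v, rep(0, 8)))
  rec <- iso_recording(ods, tt)
  expect_equal(isosbestic_average(rec)$delta_od[2], 0.25)
  # invariant to permutation of the six wavelengths
  set.seed(9)
  ods <- lapply(1:6, function(i) c(0, runif(9, -0.1, 0.3)))
  base <- isosbestic_average(iso_recording(ods, tt))$delta_od
  perm <- sample(6)
  wl <- isosbestic_wavelengths()
  intens <- do.call(rbind, lapply(seq_along(wl), function(i)
    1000 * 10^(-ods[[perm[i]]])))
  # reassign shuffled series to the (sorted) wavelength grid
  rec2 <- spectral_recording(wl, tt, intens)
  expect_equal(isosbestic_average(rec2)$delta_od, base, tolerance = 1e-12)
})

test_that("isosbestic_average reports missing spectral coverage", {
  rec <- spectral_recording(c(452, 500, 530), 0:9 / 10.5,
                            matrix(1000, 3, 10))
  expect_error(isosbestic_average(rec), "545")
})

test_that("averaging six bands suppresses OD noise by about sqrt(6)", {
  tt <- (0:599) / 10.5
  sd6 <- numeric(50); sd1 <- numeric(50)
  set.seed(42)
  for (s in 1:50) {
    ods <- lapply(1:6, function(i) {
      e <- rnorm(600, sd = 0.01)
      e - e[1]
    })
    rec <- iso_recording(ods, tt)
    avg <- isosbestic_average(rec)$delta_od
    sd6[s] <- sd(avg[-1]); sd1[s] <- sd(ods[[1]][-1])
  }
  ratio <- mean(sd1) / mean(sd6)
  expect_lt(abs(ratio - sqrt(6)) / sqrt(6), 0.15)
})

test_that("resample_uniform interpolates linearly without extrapolation", {
  tt <- (0:20) / 10.5
  rs <- resample_uniform(tt, sin(tt), rate = 10.5)
  expect_equal(rs$values, sin(tt), tolerance = 1e-12)
  # exact on affine signals even with jittered timestamps
  set.seed(1)
  tj <- sort((0:50) / 10.5 + runif(51, -0.02, 0.02))
  rs <- resample_uniform(tj, 2 + 3 * tj, rate = 10.5)
  expect_equal(rs$values, 2 + 3 * rs$timestamps, tolerance = 1e-10)
  expect_equal(mean(rs$values), 2 + 3 * mean(rs$timestamps),
               tolerance = 1e-10)
  expect_true(max(rs$timestamps) <= max(tj) + 1e-12)
  expect_error(resample_uniform(1, 2), "2 samples")
})

test_that("jittered 0.04 Hz sinusoid is reconstructed to < 1% RMS error", {
  set.seed(7)
  n <- 1260
  tj <- sort((0:(n - 1)) / 10.5 + runif(n, -0.02, 0.02))
  amp <- 0.02
  x <- amp * sin(2 * pi * 0.04 * tj)
  rs <- resample_uniform(tj, x, rate = 10.5)
  rmse <- sqrt(mean((rs$values - amp * sin(2 * pi * 0.04 * rs$timestamps))^2))
  expect_lt(rmse, 0.01 * amp)
})

test_that("domain containers validate their invariants", {
  expect_error(od_time_series(0:3, c(0.1, 0, 0, 0)), "first timestamp")
  expect_error(od_time_series(c(0, 1, 1), c(0, 1, 2)), "increasing")
  expect_error(frame_sequence(list(`450` = array(5000, c(4, 4, 2))),
                              0:1, 0.6466), "2\\^bit_depth")
  expect_error(spectral_recording(c(500, 450), 0:1, matrix(1, 2, 2)),
               "wavelengths")
  expect_error(calibration_constants(1, 1), "differ")
  tab <- hb_extinction()
  iso <- tab$is_isosbestic
  expect_true(all(tab$eps_oxy_per_mM_cm[iso] == tab$eps_deoxy_per_mM_cm[iso]))
  expect_true(all(isosbestic_wavelengths() %in% tab$wavelength_nm))
})
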