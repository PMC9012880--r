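test_that("build_sti samples the centerline at equal arc-length steps", {
  seq <- uniform_seq(42)
  seg <- capillary_segment("c", hline(2, 25, 10))
  sti <- build_sti(seq, seg)
  expect_true(all(sti$matrix == 42))
  expect_identical(ncol(sti$matrix), 15L)
  # a 100-um segment at 0.6466 um steps gives ceiling(100/0.6466) rows
  seg100 <- capillary_segment("c", hline(2, 2 + 100 / 0.6466, 10))
  sti100 <- build_sti(uniform_seq(42, nc = 200), seg100)
  expect_identical(nrow(sti100$matrix), 155L)
  expect_equal(sti100$length_um, 100, tolerance = 1e-9)
  expect_error(build_sti(seq, capillary_segment("c", hline(2, 60, 10))),
               "bounds")
})

test_that("a dark band advancing 1 px/frame traces a unit-slope stripe", {
  nr <- 20; nc <- 30; n <- 18
  stack <- array(1000, c(nr, nc, n))
  for (j in seq_len(n)) stack[, 5 + j, j] <- 100   # band at x = 4 + j (0-based)
  seq <- frame_sequence(list(`450` = stack), (seq_len(n) - 1) / 21, 1)
  sti <- build_sti(seq, capillary_segment("c", hline(4, 25, 10)),
                   position_step = 1)
  dark <- apply(sti$matrix, 2, which.min)
  expect_equal(diff(dark), rep(1, n - 1))
})

test_that("segment_tracts recovers incident intensity from plasma gaps", {
  sti <- stripe_sti(gap_val = 1000, tract_val = 500)
  seg <- segment_tracts(sti)
  expect_true(all(abs(seg$incident - 1000) / 1000 < 0.02))
  expect_true(any(seg$mask))
  # masked pixels are exactly the dark stripes
  expect_true(all(sti$matrix[seg$mask] == 500))
  # constant STI has no tracts
  expect_warning(none <- segment_tracts(make_sti(matrix(800, 40, 40))),
                 "contrast")
  expect_false(any(none$mask))
  expect_error(segment_tracts(make_sti(matrix(800, 40, 5))), "10 columns")
})

test_that("tract count matches the number of transiting RBCs", {
  cl <- quick_centerline()
  cfg <- quick_cfg(list(program_steady(cl, v = 100, rbc_spacing = 30)),
                   duration = 6, seed = 12, noise_sigma = 2)
  out <- generate_capillary_video(cfg)
  sti <- build_sti(out$sequence, capillary_segment("c", cl))
  seg <- segment_tracts(sti)
  tr <- out$truth$capillaries[[1]]
  # ground truth: RBCs whose trajectory intersects [0, L] during recording
  ds <- tr$displacement
  visited <- sum(tr$rbc_centers + max(ds) >= 0 &
                   tr$rbc_centers + min(ds) <= tr$length_um)
  expect_lte(abs(nrow(seg$tracts) - visited), 1)
})

test_that("tract_od is log10 of incident over transmitted intensity", {
  sti <- stripe_sti(gap_val = 1000, tract_val = 100)   # OD 1 tracts
  seg <- segment_tracts(sti)
  od <- tract_od(sti, seg)
  expect_equal(od$od, rep(1, nrow(od)), tolerance = 0.02)
  # equal intensities give OD 0: feed the gap-level STI with the same mask
  flat <- make_sti(matrix(1000, nrow(sti$matrix), ncol(sti$matrix)))
  od0 <- tract_od(flat, seg)
  expect_equal(od0$od, rep(0, nrow(od0)), tolerance = 1e-9)
  expect_error(tract_od(sti, list(mask = matrix(FALSE, 2, 2))), "empty")
})

test_that("rendered tract OD at 450 nm is recovered within 0.02", {
  cl <- quick_centerline()
  cfg <- quick_cfg(list(program_steady(cl, v = 100, rbc_spacing = 30)),
                   duration = 6, seed = 13)   # rbc_od_450 default 0.35
  out <- generate_capillary_video(cfg)
  sti <- build_sti(out$sequence, capillary_segment("c", cl))
  seg <- segment_tracts(sti)
  od <- tract_od(sti, seg)
  expect_lt(abs(median(od$od) - cfg$rbc_od_450), 0.02)
})

test_that("estimate_velocity reads tract slope, sign and stopped flow", {
  # static dark band: zero velocity everywhere
  m <- matrix(1000, 60, 63); m[25:32, ] <- 500
  sti <- make_sti(m)
  seg <- segment_tracts(sti)
  est <- estimate_velocity(sti, seg)
  expect_true(all(est$velocity == 0))
  # unit-slope stripes: v = slope * position_step / time_step = 13.58 um/s
  sti <- stripe_sti(slope = 1)
  est <- estimate_velocity(sti, segment_tracts(sti))
  v_expect <- 0.6466 * 21
  expect_true(all(abs(est$window_velocity - v_expect) / v_expect < 0.05))
  # negative slope gives negative velocity
  stin <- stripe_sti(slope = -1)
  estn <- estimate_velocity(stin, segment_tracts(stin))
  expect_true(all(abs(estn$window_velocity + v_expect) / v_expect < 0.05))
})

test_that("time-reversing the STI negates estimated velocities", {
  cl <- quick_centerline()
  cfg <- quick_cfg(list(program_steady(cl, v = 150)), duration = 5, seed = 19)
  sti <- build_sti(generate_capillary_video(cfg)$sequence,
                   capillary_segment("c", cl))
  fwd <- estimate_velocity(sti, segment_tracts(sti))
  rev_sti <- sti
  rev_sti$matrix <- sti$matrix[, ncol(sti$matrix):1]
  rev <- estimate_velocity(rev_sti, segment_tracts(rev_sti))
  expect_equal(rev$window_velocity, -rev(fwd$window_velocity)[seq_along(rev$window_velocity)],
               tolerance = 0.05)
})

test_that("velocity recovery holds across reversal epochs", {
  cl <- quick_centerline()
  cfg <- quick_cfg(list(program_reversed(cl, v = 150, epoch_length = 5)),
                   duration = 20, seed = 23)
  out <- generate_capillary_video(cfg)
  sti <- build_sti(out$sequence, capillary_segment("c", cl))
  est <- estimate_velocity(sti, segment_tracts(sti))
  truth_sign <- sign(out$truth$capillaries[[1]]$velocity[
    pmax(1, round(est$window_mid_s * cfg$frame_rate))])
  est_sign <- sign(est$window_velocity)
  # exclude windows straddling a sign flip
  stable <- abs(est$window_mid_s %% 5 - 2.5) < 2
  agree <- mean(est_sign[stable] == truth_sign[stable])
  expect_gte(agree, 0.95)
})

test_that("lineal density counts tract crossings per unit length", {
  mask <- matrix(FALSE, 30, 4)
  mask[c(2:4, 10:12, 20:22), 1] <- TRUE     # 3 tracts in column 1
  expect_equal(lineal_density(mask, 0.15), c(20, 0, 0, 0))
  cl <- quick_centerline()
  cfg <- quick_cfg(list(program_steady(cl, v = 150, rbc_spacing = 20)),
                   duration = 10, seed = 29)
  out <- generate_capillary_video(cfg)
  sti <- build_sti(out$sequence, capillary_segment("c", cl))
  seg <- segment_tracts(sti)
  ld <- lineal_density(seg$mask, sti$length_um / 1000)
  # closed loop against the generator's per-frame truth, and against the
  # 1/spacing expectation
  truth_ld <- out$truth$capillaries[[1]]$lineal_density
  expect_lt(abs(mean(ld) - mean(truth_ld)) / mean(truth_ld), 0.10)
  expect_lt(abs(mean(ld) - 50) / 50, 0.10)
  expect_error(lineal_density(mask, 0), "> 0")
})

test_that("hematocrit conversion follows the cylindrical-volume formula", {
  expect_equal(hematocrit_from_density(0), 0)
  expect_equal(hematocrit_from_density(50, 55, 5), 14.0, tolerance = 0.01)
  expect_equal(hematocrit_from_density(100, 55, 5),
               2 * hematocrit_from_density(50, 55, 5))
  expect_error(hematocrit_from_density(50, 55, 0), "diameter")
})

test_that("supply rate is |v| * lineal density / 1000", {
  expect_equal(supply_rate(200, 50), 10)
  expect_equal(supply_rate(0, 80), 0)
  expect_equal(supply_rate(-200, 50), 10)   # reversal still supplies RBCs
  expect_error(supply_rate(1:3, 1:2), "aligned")
})

test_that("estimated SO2 is monotone and accurate across the truth range", {
  cl <- quick_centerline()
  truths <- c(0, 0.25, 0.5, 0.75, 1)
  est <- vapply(seq_along(truths), function(i) {
    cfg <- quick_cfg(list(program_steady(cl, v = 120, so2 = truths[i])),
                     duration = 5, seed = 40 + i, dual = TRUE)
    dyn <- analyze_capillary(generate_capillary_video(cfg)$sequence,
                             capillary_segment("c", cl))
    mean(dyn$so2$so2)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_true(all(abs(est - truths) <= 0.05))
})
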