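#' Vasomotion parameters for the forward simulator
#'
#' Sinusoidal low-frequency modulation of microvascular hemoglobin content
#' (and, optionally, capillary velocity with the same phase), emulating
#' arteriolar vasomotion at roughly 2 cycles/min.
#'
#' @param enabled Logical; inject the oscillation?
#' @param period Oscillation period in seconds (> 0); default 28.8 s,
#'   i.e. 0.0347 Hz, inside the 0.03-0.06 Hz band of interest.
#' @param modulation_depth Fractional amplitude of the hemoglobin /
#'   velocity modulation, in \[0, 1).
#' @param phase Phase offset in radians.
#' @param couple_velocity Logical; modulate capillary velocity with the
#'   same phase as hemoglobin content.
#' @return Object of class `vasomotion_params`.
#' @export
vasomotion_params <- function(enabled = FALSE, period = 28.8,
                              modulation_depth = 0.05, phase = 0,
                              couple_velocity = TRUE) {
  if (period <= 0) stop("vasomotion_params: period must be > 0")
  if (modulation_depth < 0 || modulation_depth >= 1)
    stop("vasomotion_params: modulation_depth must be in [0, 1)")
  structure(list(enabled = enabled, period = period,
                 modulation_depth = modulation_depth, phase = phase,
                 couple_velocity = couple_velocity),
            class = "vasomotion_params")
}

vaso_factor <- function(vaso, t) {
  if (!vaso$enabled) return(rep(1, length(t)))
  1 + vaso$modulation_depth * sin(2 * pi * t / vaso$period + vaso$phase)
}

#' Capillary flow program for the forward simulator
#'
#' Describes one rendered capillary: its centerline (pixel coordinates,
#' arteriolar end first), a velocity program in um/s (negative = reversed,
#' venular-to-arteriolar flow), the mean center-to-center RBC spacing, an
#' SO2 program, and the ground-truth flow-state label.
#'
#' @param centerline Two-column matrix of `(x, y)` pixel coordinates
#'   (0-based), at least two points, arteriolar end first.
#' @param velocity Scalar um/s or `function(t)` returning um/s.
#' @param rbc_spacing Mean center-to-center RBC spacing in um; must exceed
#'   the rendered RBC length (6 um).
#' @param so2 Scalar fraction or `function(t)` returning fractions.
#' @param flow_state_truth `"continuous"`, `"intermittent"` or `"stopped"`.
#' @return Object of class `capillary_program`.
#' @export
capillary_program <- function(centerline, velocity = 200, rbc_spacing = 20,
                              so2 = 0.95,
                              flow_state_truth = c("continuous",
                                                   "intermittent",
                                                   "stopped")) {
  flow_state_truth <- match.arg(flow_state_truth)
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2 || ncol(centerline) != 2)
    stop("capillary_program: centerline must be an n x 2 (x, y) matrix")
  if (rbc_spacing <= RBC_LENGTH_UM)
    stop("capillary_program: rbc_spacing must exceed the RBC length (",
         RBC_LENGTH_UM, " um)")
  vfun <- if (is.function(velocity)) velocity else function(t) rep(velocity, length(t))
  sfun <- if (is.function(so2)) so2 else function(t) rep(so2, length(t))
  if (flow_state_truth == "stopped" && any(abs(vfun(seq(0, 60, 0.5))) > 0))
    stop("capillary_program: stopped program must have identically zero velocity")
  structure(list(centerline = centerline, velocity = vfun,
                 rbc_spacing = rbc_spacing, so2 = sfun,
                 flow_state_truth = flow_state_truth),
            class = "capillary_program")
}

# Rendered RBC geometry (um): elongated absorber aligned to the centerline.
RBC_LENGTH_UM <- 6
RBC_WIDTH_UM <- 5

#' Template flow programs
#'
#' Convenience constructors for the canonical flow states: steady flow,
#' intermittent flow with square-wave stops (default 4 s, satisfying the
#' "stopped > 3 s" intermittency rule), reversing flow with periodic sign
#' flips, and fully stopped flow.
#'
#' @param centerline Passed to [capillary_program()].
#' @param v Plateau speed in um/s.
#' @param stop_length Stop duration per cycle in seconds.
#' @param cycle_length Full stop/flow cycle length in seconds.
#' @param epoch_length Duration of each flow-direction epoch in seconds.
#' @param ... Further arguments to [capillary_program()].
#' @return [capillary_program()].
#' @name flow_programs
NULL

#' @rdname flow_programs
#' @export
program_steady <- function(centerline, v = 200, ...) {
  capillary_program(centerline, velocity = v,
                    flow_state_truth = "continuous", ...)
}

#' @rdname flow_programs
#' @export
program_intermittent <- function(centerline, v = 200, stop_length = 4,
                                 cycle_length = 15, ...) {
  if (stop_length >= cycle_length)
    stop("program_intermittent: stop_length must be < cycle_length")
  vfun <- function(t) ifelse(t %% cycle_length < stop_length, 0, v)
  capillary_program(centerline, velocity = vfun,
                    flow_state_truth = "intermittent", ...)
}

#' @rdname flow_programs
#' @export
program_reversed <- function(centerline, v = 200, epoch_length = 10, ...) {
  vfun <- function(t) v * ifelse((t %/% epoch_length) %% 2 == 0, 1, -1)
  capillary_program(centerline, velocity = vfun,
                    flow_state_truth = "intermittent", ...)
}

#' @rdname flow_programs
#' @export
program_stopped <- function(centerline, ...) {
  capillary_program(centerline, velocity = 0,
                    flow_state_truth = "stopped", ...)
}

#' Forward-simulation configuration
#'
#' Study conditions for the synthetic acquisitions. Defaults mirror the
#' reference acquisition: 696 x 520 px, 0.6466 um/px (450 um across 696
#' px), 21 frames/s, 12-bit, 1-min video at 438/450 nm; 2-min
#' continuous-wave spectroscopy at 10.5 recordings/s over 450-650 nm.
#'
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param pixel_size um/pixel.
#' @param frame_rate Video frame rate in Hz.
#' @param duration Video duration in seconds.
#' @param wavelengths Video wavelengths in nm.
#' @param bit_depth Camera bit depth.
#' @param background Transmitted background (plasma/tissue) intensity in
#'   counts at the start of the recording.
#' @param noise_sigma Additive Gaussian noise SD in counts; default 1% of
#'   `background`.
#' @param tissue_od Baseline tissue optical density carried by
#'   microvascular hemoglobin in the full-thickness light path; vasomotion
#'   modulates this component.
#' @param rbc_od_450 Optical density of a single RBC at 450 nm (isosbestic);
#'   the 438 nm RBC OD is `rbc_od_450` times the SO2-dependent calibration
#'   ratio so that the rendered 438/450 OD ratio matches `calib`.
#' @param calib [calibration_constants()] shared by generator and analysis.
#' @param seed Integer seed; identical configurations with identical seeds
#'   give bit-identical output.
#' @param capillary_programs List of [capillary_program()]s.
#' @param vasomotion [vasomotion_params()].
#' @param cws_rate Spectrometer sampling rate in Hz.
#' @param cws_duration Spectroscopy duration in seconds.
#' @param cws_wavelengths Spectrometer wavelength grid in nm.
#' @param cws_background Incident spectrometer intensity in counts.
#' @param cws_noise_sigma Additive Gaussian noise SD on spectrometer counts;
#'   default 1% of `cws_background`.
#' @param cws_jitter Uniform timing jitter half-width in seconds.
#' @param path_length Spectroscopy light path through the muscle in cm.
#' @param hb_concentration Baseline microvascular hemoglobin concentration
#'   in mM (tetramer) seen by the spectrometer.
#' @param tissue_so2 Mixed microvascular SO2 used for extinction at
#'   non-isosbestic wavelengths.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(frame_shape = c(520, 696), pixel_size = 0.6466,
                              frame_rate = 21, duration = 60,
                              wavelengths = c(438, 450), bit_depth = 12,
                              background = 2800, noise_sigma = NULL,
                              tissue_od = 0.3, rbc_od_450 = 0.35,
                              calib = calibration_constants(), seed = 1L,
                              capillary_programs = list(),
                              vasomotion = vasomotion_params(),
                              cws_rate = 10.5, cws_duration = 120,
                              cws_wavelengths = 450:650,
                              cws_background = 3000,
                              cws_noise_sigma = NULL, cws_jitter = 0.02,
                              path_length = 0.1, hb_concentration = 0.1,
                              tissue_so2 = 0.7) {
  if (frame_rate <= 0 || duration <= 0 || cws_rate <= 0 || cws_duration <= 0)
    stop("simulation_config: rates and durations must be > 0")
  if (is.null(noise_sigma)) noise_sigma <- 0.01 * background
  if (is.null(cws_noise_sigma)) cws_noise_sigma <- 0.01 * cws_background
  stopifnot(inherits(vasomotion, "vasomotion_params"),
            inherits(calib, "calibration_constants"))
  structure(list(frame_shape = frame_shape, pixel_size = pixel_size,
                 frame_rate = frame_rate, duration = duration,
                 wavelengths = wavelengths, bit_depth = bit_depth,
                 background = background, noise_sigma = noise_sigma,
                 tissue_od = tissue_od, rbc_od_450 = rbc_od_450,
                 calib = calib, seed = as.integer(seed),
                 capillary_programs = capillary_programs,
                 vasomotion = vasomotion, cws_rate = cws_rate,
                 cws_duration = cws_duration,
                 cws_wavelengths = cws_wavelengths,
                 cws_background = cws_background,
                 cws_noise_sigma = cws_noise_sigma, cws_jitter = cws_jitter,
                 path_length = path_length,
                 hb_concentration = hb_concentration,
                 tissue_so2 = tissue_so2),
            class = "simulation_config")
}

# RBC optical density at a video wavelength for saturation so2. At the
# isosbestic 450 nm the OD is saturation-independent; at 438 nm the OD is
# rbc_od_450 times the calibration ratio interpolated between its deoxy
# (SO2 = 0) and oxy (SO2 = 1) endpoints, so forward model and SO2
# inversion share one calibration.
rbc_od_at <- function(config, wavelength, so2) {
  if (abs(wavelength - 450) < 1) return(rep(config$rbc_od_450, length(so2)))
  if (abs(wavelength - 438) < 1) {
    r <- config$calib$ratio_deoxy +
      (config$calib$ratio_oxy - config$calib$ratio_deoxy) * so2
    return(config$rbc_od_450 * r)
  }
  stop("rbc_od_at: no RBC extinction model at ", wavelength, " nm")
}

# Dense arc-length parameterization of a polyline (0-based pixel coords).
# Returns matrix with columns x, y, s (s in um).
densify_centerline <- function(centerline, pixel_size, step_px = 0.25) {
  segs <- diff(centerline)
  len_px <- sqrt(rowSums(segs^2))
  cum <- c(0, cumsum(len_px))
  total <- cum[length(cum)]
  s_px <- seq(0, total, by = step_px)
  if (s_px[length(s_px)] < total) s_px <- c(s_px, total)
  idx <- findInterval(s_px, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(segs))
  frac <- (s_px - cum[idx]) / len_px[idx]
  cbind(x = centerline[idx, 1] + frac * segs[idx, 1],
        y = centerline[idx, 2] + frac * segs[idx, 2],
        s = s_px * pixel_size)
}

# Tube geometry for one capillary: candidate pixels near the centerline
# with their arc coordinate (um) and transverse distance (um).
tube_geometry <- function(centerline, frame_shape, pixel_size) {
  dense <- densify_centerline(centerline, pixel_size)
  hw_px <- ceiling((RBC_WIDTH_UM / pixel_size) / 2 + 1.5)
  offs <- as.matrix(expand.grid(dx = -hw_px:hw_px, dy = -hw_px:hw_px))
  base <- unique(round(dense[, c("x", "y")]))
  cand <- unique(cbind(rep(base[, 1], each = nrow(offs)) + offs[, 1],
                       rep(base[, 2], each = nrow(offs)) + offs[, 2]))
  keep <- cand[, 1] >= 0 & cand[, 1] <= frame_shape[2] - 1 &
    cand[, 2] >= 0 & cand[, 2] <= frame_shape[1] - 1
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) stop("tube_geometry: capillary outside frame")
  # nearest dense sample per candidate (chunked distance computation)
  n <- nrow(cand)
  s_um <- numeric(n); d_um <- numeric(n)
  chunk <- 4000L
  for (i0 in seq(1L, n, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, n)
    dx <- outer(cand[ii, 1], dense[, "x"], "-")
    dy <- outer(cand[ii, 2], dense[, "y"], "-")
    d2 <- dx * dx + dy * dy
    j <- max.col(-d2, ties.method = "first")
    s_um[ii] <- dense[j, "s"]
    d_um[ii] <- sqrt(d2[cbind(seq_along(ii), j)]) * pixel_size
  }
  keep <- d_um <= RBC_WIDTH_UM / 2 + pixel_size
  list(col = cand[keep, 1] + 1L, row = cand[keep, 2] + 1L,
       s = s_um[keep], d = d_um[keep],
       length_um = unname(dense[nrow(dense), "s"]))
}

# Seed RBC center positions (um along the tube, possibly outside [0, L])
# covering the whole displacement range. Center-to-center spacings are
# uniform in [0.5, 1.5] x the requested mean (floored at 1.2 x RBC
# length): aperiodic enough to avoid aliasing in the orientation search,
# with bounded dispersion so realized lineal density stays close to
# 1/spacing.
seed_rbc_centers <- function(spacing, length_um, drift_range) {
  lo <- -max(drift_range[2], 0) - 3 * spacing
  hi <- length_um - min(drift_range[1], 0) + 3 * spacing
  n_max <- ceiling((hi - lo) / spacing * 2) + 10
  gaps <- pmax(1.2 * RBC_LENGTH_UM,
               stats::runif(n_max, 0.5 * spacing, 1.5 * spacing))
  centers <- lo + cumsum(gaps)
  centers[centers <= hi]
}

# Fractional RBC coverage of pixels with arc coordinates s (um), given
# sorted RBC centers shifted into the frame's reference (one-pixel
# anti-aliasing ramp in both axes).
rbc_coverage <- function(s, centers, d_um, pixel_size) {
  if (!length(centers)) return(numeric(length(s)))
  j <- findInterval(s, centers)
  d_lo <- ifelse(j >= 1, s - centers[pmax(j, 1)], Inf)
  d_hi <- ifelse(j < length(centers), centers[pmin(j + 1, length(centers))] - s, Inf)
  ds <- pmin(d_lo, d_hi)
  cov_s <- pmin(1, pmax(0, ((RBC_LENGTH_UM + pixel_size) / 2 - ds) / pixel_size))
  cov_t <- pmin(1, pmax(0, ((RBC_WIDTH_UM + pixel_size) / 2 - d_um) / pixel_size))
  cov_s * cov_t
}

#' Simulate a dual-wavelength capillary video
#'
#' Renders each capillary program as dark, elongated Beer-Lambert absorbers
#' (RBCs) moving along the centerline, separated by bright plasma gaps, on
#' a tissue background whose transmitted intensity optionally oscillates
#' with vasomotion. Per-wavelength attenuation is saturation-dependent at
#' 438 nm and saturation-independent at 450 nm. Additive Gaussian noise is
#' applied, and counts are rounded and clipped to the camera bit depth.
#'
#' @param config [simulation_config()]; if it contains no capillary
#'   programs, one steady horizontal capillary across the frame middle is
#'   used.
#' @return List with elements `sequence` (a [frame_sequence()]) and
#'   `truth`, a list with per-capillary ground truth: per-frame effective
#'   velocity (um/s), displacement (um), lineal density (RBC/mm), supply
#'   rate (RBC/s), SO2, the seeded RBC centers, the tube length (um) and
#'   the number of midpoint crossings.
#' @export
generate_capillary_video <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  n <- round(config$duration * config$frame_rate)
  t <- (seq_len(n) - 1) / config$frame_rate
  dt <- 1 / config$frame_rate
  programs <- config$capillary_programs
  if (!length(programs)) {
    margin <- 4
    cl <- cbind(c(margin, nc - 1 - margin), c((nr - 1) / 2, (nr - 1) / 2))
    programs <- list(program_steady(cl))
  }
  vf <- vaso_factor(config$vasomotion, t)
  vf_vel <- if (config$vasomotion$couple_velocity) vf else rep(1, n)
  # background transmitted intensity: vasomotion modulates the
  # hemoglobin-borne part of the tissue OD
  od_bg <- config$tissue_od * vf
  i_bg <- config$background * 10^(-(od_bg - od_bg[1]))

  caps <- lapply(programs, function(p) {
    geom <- tube_geometry(p$centerline, config$frame_shape, config$pixel_size)
    v <- p$velocity(t) * vf_vel
    ds <- c(0, cumsum(v[-n] * dt))
    centers <- seed_rbc_centers(p$rbc_spacing, geom$length_um, range(ds))
    so2 <- p$so2(t)
    # ground truth per frame: RBCs inside [0, L]
    len_mm <- geom$length_um / 1000
    ld <- vapply(seq_len(n), function(j) {
      sum(centers + ds[j] >= 0 & centers + ds[j] <= geom$length_um) / len_mm
    }, numeric(1))
    mid <- geom$length_um / 2
    crossings <- 0L
    if (n > 1) {
      p0 <- mid - ds[-n]; p1 <- mid - ds[-1]
      for (j in seq_len(n - 1)) {
        lo <- min(p0[j], p1[j]); hi <- max(p0[j], p1[j])
        crossings <- crossings + sum(centers > lo & centers <= hi)
      }
    }
    list(program = p, geom = geom, v = v, ds = ds, centers = centers,
         so2 = so2, lineal_density = ld,
         supply_rate = abs(v) * ld / 1000, midpoint_crossings = crossings)
  })

  sat <- 2^config$bit_depth - 1
  frame_len <- nr * nc
  stacks <- lapply(config$wavelengths, function(wl) {
    arr <- array(rep(i_bg, each = frame_len), dim = c(nr, nc, n))
    for (j in seq_len(n)) {
      off <- (j - 1) * frame_len
      for (cp in caps) {
        cov <- rbc_coverage(cp$geom$s - cp$ds[j], cp$centers, cp$geom$d,
                            config$pixel_size)
        od_rbc <- rbc_od_at(config, wl, cp$so2[j])
        idx <- off + (cp$geom$col - 1L) * nr + cp$geom$row
        # multiplicative attenuation so overlapping capillaries sum in OD
        arr[idx] <- arr[idx] * 10^(-cov * od_rbc)
      }
    }
    if (config$noise_sigma > 0)
      arr <- arr + stats::rnorm(length(arr), sd = config$noise_sigma)
    array(pmin(sat, pmax(0, round(arr))), dim = c(nr, nc, n))
  })
  names(stacks) <- as.character(config$wavelengths)

  seq <- frame_sequence(stacks, t, pixel_size = config$pixel_size,
                        bit_depth = config$bit_depth)
  truth <- list(
    timestamps = t,
    capillaries = lapply(caps, function(cp) {
      list(flow_state = cp$program$flow_state_truth,
           velocity = cp$v, displacement = cp$ds,
           lineal_density = cp$lineal_density,
           supply_rate = cp$supply_rate, so2 = cp$so2,
           rbc_centers = cp$centers, length_um = cp$geom$length_um,
           midpoint_crossings = cp$midpoint_crossings)
    }),
    vasomotion = config$vasomotion)
  list(sequence = seq, truth = truth)
}

#' Simulate a continuous-wave spectroscopy recording
#'
#' Hemoglobin concentration follows
#' `C(t) = C0 * (1 + m * sin(2*pi*t/T + phi))` when vasomotion is enabled
#' and stays constant otherwise; transmitted intensities follow
#' `I_lambda(t) = I0 * 10^(-eps(lambda) * L * C(t))` with additive Gaussian
#' noise, on timestamps jittered around the nominal sampling rate.
#'
#' @param config [simulation_config()].
#' @return List with `recording` (a [spectral_recording()]) and `truth`
#'   (concentration trace, period, modulation depth).
#' @export
generate_cws_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- round(config$cws_duration * config$cws_rate)
  t <- (seq_len(n) - 1) / config$cws_rate +
    stats::runif(n, -config$cws_jitter, config$cws_jitter)
  t <- t - t[1]
  if (any(diff(t) <= 0))
    stop("generate_cws_recording: cws_jitter too large for the sampling rate")
  conc <- config$hb_concentration * vaso_factor(config$vasomotion, t)
  eps <- eps_at(config$cws_wavelengths, so2 = config$tissue_so2)
  od <- outer(eps * config$path_length, conc)   # wavelength x time
  intens <- config$cws_background * 10^(-od)
  if (config$cws_noise_sigma > 0)
    intens <- intens + matrix(stats::rnorm(length(intens),
                                           sd = config$cws_noise_sigma),
                              nrow = nrow(intens))
  intens <- pmax(intens, 0)
  rec <- spectral_recording(config$cws_wavelengths, t, intens)
  truth <- list(concentration = conc,
                period = if (config$vasomotion$enabled)
                  config$vasomotion$period else NA_real_,
                modulation_depth = if (config$vasomotion$enabled)
                  config$vasomotion$modulation_depth else 0)
  list(recording = rec, truth = truth)
}

#' Simulate a two-group cohort across three imaging periods
#'
#' Builds a control and a FIP (feces-induced peritonitis) group of
#' `n_per_group` animals with `fovs_per_animal` fields of view, each
#' recorded over three imaging periods. Control fields never oscillate; in
#' the FIP group, a random subset of fields (fraction `osc_fraction`)
#' develops vasomotion from period 2 onward with a per-field period drawn
#' uniformly in `period_range` and depth in `depth_range` — the remainder
#' stays non-oscillatory, mirroring the heterogeneity of dysfunction
#' across a muscle.
#'
#' @param n_per_group Animals per group (>= 1).
#' @param fovs_per_animal Fields of view per animal (>= 1).
#' @param seed Integer seed for the whole cohort.
#' @param base_config [simulation_config()] template for every recording.
#' @param osc_fraction Fraction of FIP fields that develop oscillations.
#' @param period_range Range (s) of injected vasomotion periods.
#' @param depth_range Range of injected modulation depths.
#' @param include_video Also generate the dual-wavelength video for each
#'   field/period (slow; intended for small frame shapes).
#' @return List with `manifest` (data.frame: `fov_id, animal_id,
#'   group_label, imaging_period, oscillatory, true_period,
#'   true_depth`), `recordings` (list of [spectral_recording()], one per
#'   manifest row) and, if requested, `videos` (list of
#'   [frame_sequence()]).
#' @export
generate_cohort <- function(n_per_group = 5, fovs_per_animal = 8, seed = 1L,
                            base_config = simulation_config(),
                            osc_fraction = 0.7, period_range = c(16, 32),
                            depth_range = c(0.03, 0.07),
                            include_video = FALSE) {
  if (n_per_group < 1 || fovs_per_animal < 1)
    stop("generate_cohort: counts must be >= 1")
  set.seed(seed)
  groups <- c("control", "FIP")
  fov_tab <- expand.grid(fov = seq_len(fovs_per_animal),
                         animal = seq_len(n_per_group),
                         group = groups, stringsAsFactors = FALSE)
  fov_tab$animal_id <- paste0(substr(fov_tab$group, 1, 1), fov_tab$animal)
  fov_tab$fov_id <- paste0(fov_tab$animal_id, "_fov", fov_tab$fov)
  fov_tab$oscillatory <- fov_tab$group == "FIP" &
    stats::runif(nrow(fov_tab)) < osc_fraction
  fov_tab$true_period <- ifelse(fov_tab$oscillatory,
                                stats::runif(nrow(fov_tab), period_range[1],
                                             period_range[2]), NA_real_)
  fov_tab$true_depth <- ifelse(fov_tab$oscillatory,
                               stats::runif(nrow(fov_tab), depth_range[1],
                                            depth_range[2]), NA_real_)
  rec_seeds <- sample.int(2^30, nrow(fov_tab) * 3)

  manifest <- do.call(rbind, lapply(1:3, function(p) {
    data.frame(fov_id = fov_tab$fov_id, animal_id = fov_tab$animal_id,
               group_label = fov_tab$group, imaging_period = p,
               oscillatory = fov_tab$oscillatory & p >= 2,
               true_period = ifelse(fov_tab$oscillatory & p >= 2,
                                    fov_tab$true_period, NA_real_),
               true_depth = ifelse(fov_tab$oscillatory & p >= 2,
                                   fov_tab$true_depth, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL

  recordings <- vector("list", nrow(manifest))
  videos <- if (include_video) vector("list", nrow(manifest)) else NULL
  for (i in seq_len(nrow(manifest))) {
    cfg <- base_config
    cfg$seed <- rec_seeds[i]
    cfg$vasomotion <- if (manifest$oscillatory[i])
      vasomotion_params(TRUE, period = manifest$true_period[i],
                        modulation_depth = manifest$true_depth[i],
                        phase = stats::runif(1, 0, 2 * pi))
    else vasomotion_params(FALSE)
    out <- generate_cws_recording(cfg)
    rec <- out$recording
    rec$fov_id <- manifest$fov_id[i]
    rec$group_label <- manifest$group_label[i]
    rec$imaging_period <- manifest$imaging_period[i]
    recordings[[i]] <- rec
    if (include_video) {
      vid <- generate_capillary_video(cfg)$sequence
      vid$fov_id <- manifest$fov_id[i]
      vid$group_label <- manifest$group_label[i]
      vid$imaging_period <- manifest$imaging_period[i]
      videos[[i]] <- vid
    }
  }
  out <- list(manifest = manifest, recordings = recordings)
  if (include_video) out$videos <- videos
  out
}
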