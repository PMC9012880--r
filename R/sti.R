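#' Capillary segment (centerline) definition
#'
#' An ordered pixel polyline tracing one in-focus capillary, arteriolar
#' end first. Position 0 of the derived space-time image is the first
#' point; positive velocity means arteriolar-to-venular flow.
#'
#' @param capillary_id Identifier.
#' @param points Two-column matrix of `(x, y)` pixel coordinates
#'   (0-based), at least two points.
#' @param fov_id Field-of-view identifier.
#' @param pixel_size Optional um/pixel, used to record the physical
#'   length; otherwise length is attached when an STI is built.
#' @return Object of class `capillary_segment`.
#' @export
capillary_segment <- function(capillary_id, points, fov_id = "fov",
                              pixel_size = NA_real_) {
  points <- as.matrix(points)
  if (nrow(points) < 2 || ncol(points) != 2)
    stop("capillary_segment: points must be an n x 2 (x, y) matrix")
  len_px <- sum(sqrt(rowSums(diff(points)^2)))
  structure(list(capillary_id = capillary_id, points = points,
                 fov_id = fov_id, length_px = len_px,
                 length_um = len_px * pixel_size),
            class = "capillary_segment")
}

#' Build a space-time image along a capillary centerline
#'
#' For each video frame, the intensity is sampled (bilinearly) at equal
#' arc-length steps along the centerline; each frame contributes one
#' column, so moving RBCs appear as sloped dark tracts whose slope encodes
#' velocity.
#'
#' @param seq [frame_sequence()].
#' @param segment [capillary_segment()] within the frame bounds.
#' @param wavelength Wavelength (nm) of the stack to sample.
#' @param position_step Arc-length step in um (default: one pixel).
#' @return Object of class `space_time_image` with fields `matrix`
#'   (position x time), `position_step` (um), `time_step` (s),
#'   `timestamps`, `wavelength`, `capillary_id`, `length_um`.
#' @export
build_sti <- function(seq, segment, wavelength = 450,
                      position_step = seq$pixel_size) {
  stopifnot(inherits(seq, "frame_sequence"),
            inherits(segment, "capillary_segment"))
  stack <- wavelength_stack(seq, wavelength)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; n <- dim(stack)[3]
  dense <- densify_centerline(segment$points, seq$pixel_size)
  length_um <- unname(dense[nrow(dense), "s"])
  n_pos <- ceiling(length_um / position_step)
  s_target <- (seq_len(n_pos) - 1) * position_step
  x <- stats::approx(dense[, "s"], dense[, "x"], xout = s_target)$y
  y <- stats::approx(dense[, "s"], dense[, "y"], xout = s_target)$y
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1))
    stop("build_sti: centerline sample outside frame bounds")
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i11 <- (x0) * nr + y0 + 1          # row y0+1, col x0+1 (1-based linear)
  i21 <- i11 + 1                     # row below
  i12 <- i11 + nr                    # col right
  i22 <- i12 + 1
  w11 <- (1 - fx) * (1 - fy); w21 <- (1 - fx) * fy
  w12 <- fx * (1 - fy); w22 <- fx * fy
  m <- matrix(0, n_pos, n)
  frame_len <- nr * nc
  for (j in seq_len(n)) {
    off <- (j - 1) * frame_len
    m[, j] <- w11 * stack[i11 + off] + w21 * stack[i21 + off] +
      w12 * stack[i12 + off] + w22 * stack[i22 + off]
  }
  dtv <- diff(seq$timestamps)
  structure(list(matrix = m, position_step = position_step,
                 time_step = stats::median(dtv),
                 timestamps = seq$timestamps, wavelength = wavelength,
                 capillary_id = segment$capillary_id,
                 length_um = length_um),
            class = "space_time_image")
}

#' @export
print.space_time_image <- function(x, ...) {
  cat(sprintf(
    "<space_time_image> capillary %s at %g nm: %d positions x %d frames (%.1f um, %.1f s)\n",
    x$capillary_id, x$wavelength, nrow(x$matrix), ncol(x$matrix),
    x$length_um, ncol(x$matrix) * x$time_step))
  invisible(x)
}

# 90th-percentile background (incident-intensity) surface estimated on a
# time x position block grid and bilinearly interpolated back to the full
# STI; blocks default to 1 s x 10 um.
incident_surface <- function(m, position_step, time_step,
                             block_s = 1, block_um = 10, prob = 0.9) {
  nrw <- max(1L, min(nrow(m), round(block_um / position_step)))
  ncw <- max(1L, min(ncol(m), round(block_s / time_step)))
  r_starts <- seq(1L, nrow(m), by = nrw)
  c_starts <- seq(1L, ncol(m), by = ncw)
  q <- matrix(0, length(r_starts), length(c_starts))
  r_mid <- numeric(length(r_starts)); c_mid <- numeric(length(c_starts))
  for (a in seq_along(r_starts)) {
    rr <- r_starts[a]:min(r_starts[a] + nrw - 1L, nrow(m))
    r_mid[a] <- mean(rr)
    for (b in seq_along(c_starts)) {
      cc <- c_starts[b]:min(c_starts[b] + ncw - 1L, ncol(m))
      if (a == 1) c_mid[b] <- mean(cc)
      q[a, b] <- stats::quantile(m[rr, cc], prob, names = FALSE)
    }
  }
  interp_axis <- function(known_pos, vals, out_pos) {
    if (length(known_pos) == 1) return(matrix(vals, length(out_pos),
                                              ncol(as.matrix(vals)),
                                              byrow = TRUE))
    apply(as.matrix(vals), 2, function(v)
      stats::approx(known_pos, v, xout = out_pos, rule = 2)$y)
  }
  tmp <- interp_axis(r_mid, q, seq_len(nrow(m)))          # rows expanded
  t(interp_axis(c_mid, t(tmp), seq_len(ncol(m))))         # cols expanded
}

#' Segment RBC tracts and estimate the incident-intensity surface
#'
#' The incident (plasma) intensity is estimated per pixel as a
#' high-percentile surface of the STI — plasma gaps between RBCs carry the
#' unattenuated light level. The STI is divided by this surface and
#' thresholded (Otsu) to separate dark RBC tracts from bright plasma;
#' connected components below `min_px` pixels are discarded as noise.
#'
#' @param sti [build_sti()] output with at least 10 columns.
#' @param min_px Minimum tract size in pixels.
#' @param block_s,block_um Block size (seconds, um) of the percentile grid.
#' @param contrast_floor If the normalized STI's 5-95% spread is below
#'   this value the STI is treated as tract-free (warning, empty mask).
#' @return List with `mask` (logical matrix), `label` (integer matrix of
#'   connected components), `incident` (numeric matrix), `normalized`, and
#'   `tracts` (data.frame: `tract_id, n_px, t_mid_s, orientation_sign`).
#' @export
segment_tracts <- function(sti, min_px = 5, block_s = 1, block_um = 10,
                           contrast_floor = 0.05) {
  stopifnot(inherits(sti, "space_time_image"))
  m <- sti$matrix
  if (ncol(m) < 10) stop("segment_tracts: STI must have >= 10 columns")
  inc <- incident_surface(m, sti$position_step, sti$time_step,
                          block_s, block_um)
  norm <- m / pmax(inc, .Machine$double.eps)
  spread <- diff(stats::quantile(norm, c(0.05, 0.95), names = FALSE))
  if (spread < contrast_floor) {
    warning("segment_tracts: STI has no intensity contrast; no tracts found")
    empty <- matrix(FALSE, nrow(m), ncol(m))
    return(list(mask = empty, label = matrix(0L, nrow(m), ncol(m)),
                incident = inc, normalized = norm,
                tracts = data.frame(tract_id = integer(), n_px = integer(),
                                    t_mid_s = numeric(),
                                    orientation_sign = numeric())))
  }
  lo <- min(norm); hi <- max(norm)
  thr <- EBImage::otsu(matrix((norm - lo) / (hi - lo), nrow(norm)),
                       range = c(0, 1)) * (hi - lo) + lo
  mask <- norm < thr
  label <- EBImage::bwlabel(mask)
  sizes <- tabulate(label[label > 0])
  keep <- which(sizes >= min_px)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  label[label > 0] <- relabel[label[label > 0]]
  mask <- label > 0
  tracts <- if (length(keep)) {
    idx <- which(label > 0)
    lab <- label[idx]
    rr <- (idx - 1) %% nrow(m) + 1
    cc <- (idx - 1) %/% nrow(m) + 1
    n_px <- tabulate(lab)
    sr <- rowsum(rr, lab)[, 1]; sc <- rowsum(cc, lab)[, 1]
    src <- rowsum(rr * cc, lab)[, 1]
    # principal orientation sign from the position~time covariance
    covar <- src - sr * sc / n_px
    data.frame(tract_id = seq_along(n_px), n_px = n_px,
               t_mid_s = sti$timestamps[pmax(1L, round(sc / n_px))],
               orientation_sign = sign(covar))
  } else {
    data.frame(tract_id = integer(), n_px = integer(), t_mid_s = numeric(),
               orientation_sign = numeric())
  }
  list(mask = mask, label = label, incident = inc, normalized = norm,
       tracts = tracts)
}

#' Optical density of each segmented RBC tract
#'
#' Per tract, `OD = log10(I0 / I_RBC)`, where `I_RBC` is the mean STI
#' intensity over the tract's core pixels and `I0` the mean of the
#' incident-intensity surface over the same pixels. The core is the darker
#' half of the tract (normalized intensity at or below the tract median),
#' which suppresses the partial-volume dilution of anti-aliased tract
#' edges.
#'
#' @param sti [build_sti()] output.
#' @param seg [segment_tracts()] output (its `label` and `incident` are
#'   used; they may come from the matched STI at the other wavelength so
#'   tracts correspond across wavelengths).
#' @return data.frame `tract_id, od, i_rbc, i0, t_mid_s`.
#' @export
tract_od <- function(sti, seg) {
  stopifnot(inherits(sti, "space_time_image"))
  if (!any(seg$mask)) stop("tract_od: empty tract mask")
  inc <- incident_surface(sti$matrix, sti$position_step, sti$time_step)
  norm <- sti$matrix / pmax(inc, .Machine$double.eps)
  idx <- which(seg$label > 0)
  lab <- seg$label[idx]
  med <- vapply(split(norm[idx], lab), stats::median, numeric(1))
  core <- norm[idx] <= med[as.character(lab)]
  ci <- idx[core]; cl <- lab[core]
  n_core <- tabulate(cl)
  ids <- which(n_core > 0)
  i_rbc <- rowsum(sti$matrix[ci], cl)[, 1] / n_core[ids]
  i0 <- rowsum(inc[ci], cl)[, 1] / n_core[ids]
  if (any(i_rbc <= 0) || any(i0 <= 0))
    stop("tract_od: nonpositive intensity in tract ",
         ids[which(i_rbc <= 0 | i0 <= 0)[1]])
  cols <- rowsum((ci - 1) %/% nrow(sti$matrix) + 1, cl)[, 1] / n_core[ids]
  data.frame(tract_id = ids, od = log10(i0 / i_rbc), i_rbc = i_rbc, i0 = i0,
             t_mid_s = sti$timestamps[pmax(1L, round(cols))],
             row.names = NULL)
}

# Shear-projection score for tract orientation. Pixels of the demeaned
# tract mask are sheared by the candidate slope (rows per column) onto
# the position axis (unit bins, linear fractional weights); tracts
# aligned with the slope collapse into few bins, maximizing the
# count-weighted projection variance sum(S_b^2 / C_b). The score is
# null-centered by subtracting the expected random-mask contribution
# p(1-p) per occupied bin: without centering, steep slopes that shatter
# the window into near-singleton bins reach the same raw score as true
# alignment (both equal N p (1-p)), making the raw objective degenerate.
shear_score <- function(vals, rows, cols, slope, p) {
  y <- rows - slope * cols
  y0 <- floor(y); w <- y - y0
  idx <- c(y0, y0 + 1L) - min(y0) + 1L
  s <- rowsum(c(vals * (1 - w), vals * w), idx)
  cnt <- rowsum(c(1 - w, w), idx)
  ok <- cnt > 1e-9
  sum(s[ok]^2 / cnt[ok]) - p * (1 - p) * sum(ok)
}

#' Estimate signed RBC velocity from a space-time image
#'
#' Within tiled windows of `window` seconds, the dominant tract
#' orientation is found by a Radon-style angle search: the binary tract
#' mask is sheared over a grid of candidate angles and the angle
#' maximizing the projection variance is refined continuously within one
#' grid step. Velocity is `tan(theta) * position_step / time_step`, signed
#' so that positive means arteriolar-to-venular flow; windows whose best
#' speed falls below `v_stop` (or that contain no tracts) are assigned
#' exactly 0, the convention for stopped flow.
#'
#' @param sti [build_sti()] output.
#' @param seg [segment_tracts()] output for the same STI.
#' @param window Window length in seconds (>= 3 frames).
#' @param angle_step Coarse angle grid step in degrees.
#' @param v_stop Stopped-flow threshold in um/s.
#' @return List with `timestamps`, `velocity` (um/s per frame),
#'   `window_velocity` and `window_mid_s` (per analysis window).
#' @export
estimate_velocity <- function(sti, seg, window = 0.5, angle_step = 0.5,
                              v_stop = 10) {
  stopifnot(inherits(sti, "space_time_image"))
  n <- ncol(sti$matrix); nr <- nrow(sti$matrix)
  nwc <- max(3L, round(window / sti$time_step))
  if (n < nwc) stop("estimate_velocity: STI shorter than one window")
  starts <- seq(1L, n - nwc + 1L, by = nwc)
  scale <- sti$position_step / sti$time_step   # um/s per (row/col) of slope
  angles <- seq(-89.5, 89.5, by = angle_step)
  win_v <- numeric(length(starts)); win_t <- numeric(length(starts))
  vel <- numeric(n)
  rows_all <- rep(seq_len(nr), nwc)
  cols_all <- rep(seq_len(nwc), each = nr)
  slopes <- tan(angles * pi / 180)
  # per-angle background bin counts (rounded shear) depend only on the
  # window geometry; precompute once
  bg <- lapply(slopes, function(s) {
    y <- as.integer(round(rows_all - s * cols_all))
    off <- min(y)
    cnt <- tabulate(y - off + 1L)
    ok <- cnt > 0L
    list(off = off, nbins = length(cnt), ok = ok, cnt_ok = cnt[ok],
         n_ok = sum(ok))
  })
  for (k in seq_along(starts)) {
    cc <- starts[k]:(starts[k] + nwc - 1L)
    win_t[k] <- mean(sti$timestamps[cc])
    sub <- seg$mask[, cc, drop = FALSE]
    npx <- sum(sub)
    v_hat <- 0
    if (npx >= 10 && npx < length(sub)) {
      px <- which(sub, arr.ind = TRUE)
      p <- npx / length(sub)
      # coarse grid: null-centered integer-binned projection score
      pr <- px[, 1]; pc <- px[, 2]
      score <- vapply(seq_along(slopes), function(a) {
        b <- bg[[a]]
        y <- as.integer(round(pr - slopes[a] * pc)) - b$off + 1L
        m_cnt <- tabulate(y, nbins = b$nbins)[b$ok]
        sum((m_cnt - p * b$cnt_ok)^2 / b$cnt_ok) - p * (1 - p) * b$n_ok
      }, numeric(1))
      i_best <- which.max(score)
      lo <- angles[max(1L, i_best - 1L)]
      hi <- angles[min(length(angles), i_best + 1L)]
      # continuous refinement with fractional binning
      vals <- as.numeric(sub) - p
      obj <- function(theta)
        shear_score(vals, rows_all, cols_all, tan(theta * pi / 180), p)
      ref <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                             tol = 5e-3)
      v_hat <- tan(ref$maximum * pi / 180) * scale
      if (abs(v_hat) < v_stop) v_hat <- 0
    }
    win_v[k] <- v_hat
    vel[cc] <- v_hat
  }
  # trailing frames not covered by a full window inherit the last estimate
  last_end <- starts[length(starts)] + nwc - 1L
  if (last_end < n) vel[(last_end + 1L):n] <- win_v[length(win_v)]
  list(timestamps = sti$timestamps, velocity = vel,
       window_velocity = win_v, window_mid_s = win_t)
}

#' Lineal density series from a tract mask
#'
#' Per time column, the number of distinct RBC tracts crossing that column
#' (contiguous runs of masked pixels) divided by the segment length.
#'
#' @param mask Logical position x time matrix from [segment_tracts()].
#' @param segment_length_mm Capillary segment length in mm (> 0).
#' @return Numeric vector, RBC/mm per frame.
#' @export
lineal_density <- function(mask, segment_length_mm) {
  if (segment_length_mm <= 0)
    stop("lineal_density: segment_length_mm must be > 0")
  apply(mask, 2, function(col) {
    r <- rle(col)
    sum(r$values) / segment_length_mm
  })
}

#' Convert lineal density to tube hematocrit
#'
#' `Hct (%) = 100 * ld * V_rbc / (pi * (d/2)^2 * 1000)`, with lineal
#' density `ld` in RBC/mm, RBC volume in fL (= um^3) and capillary
#' diameter in um. Defaults: rat RBC volume 55 fL, diameter 5 um
#' (configurable).
#'
#' @param ld Lineal density, RBC/mm.
#' @param rbc_volume RBC volume in fL.
#' @param capillary_diameter Capillary diameter in um (> 0).
#' @return Hematocrit in percent.
#' @export
hematocrit_from_density <- function(ld, rbc_volume = 55,
                                    capillary_diameter = 5) {
  if (capillary_diameter <= 0)
    stop("hematocrit_from_density: capillary_diameter must be > 0")
  100 * ld * rbc_volume / (pi * (capillary_diameter / 2)^2 * 1000)
}

#' RBC supply rate
#'
#' `SR = |velocity| * lineal density / 1000` (RBC/s); stopped frames
#' (velocity 0) give 0 by construction.
#'
#' @param velocity Signed velocity in um/s.
#' @param ld Lineal density in RBC/mm (same length).
#' @return RBC/s series.
#' @export
supply_rate <- function(velocity, ld) {
  if (length(velocity) != length(ld))
    stop("supply_rate: velocity and ld must be aligned")
  abs(velocity) * ld / 1000
}

#' Per-tract oxygen saturation from matched dual-wavelength STIs
#'
#' Applies the 438/450 nm OD-ratio calibration to tract ODs measured on
#' the two wavelength STIs of the same capillary with a shared tract
#' segmentation (so tracts are matched by construction). Tracts with
#' nonpositive 450 nm OD carry no usable signal and are skipped with a
#' message.
#'
#' @param od438,od450 [tract_od()] outputs for the 438 and 450 nm STIs
#'   with a shared segmentation.
#' @param calib [calibration_constants()].
#' @return data.frame `tract_id, t_mid_s, so2`.
#' @export
tract_so2 <- function(od438, od450, calib = calibration_constants()) {
  m <- merge(od438[, c("tract_id", "od")],
             od450[, c("tract_id", "od", "t_mid_s")],
             by = "tract_id", suffixes = c("_438", "_450"))
  usable <- m$od_450 > 0
  if (any(!usable))
    message("tract_so2: skipping ", sum(!usable),
            " tract(s) with nonpositive 450 nm OD")
  m <- m[usable, , drop = FALSE]
  data.frame(tract_id = m$tract_id, t_mid_s = m$t_mid_s,
             so2 = rbc_so2(m$od_438, m$od_450, calib))
}

#' Full per-capillary hemodynamics from a dual-wavelength sequence
#'
#' Convenience pipeline: builds the 450 nm STI, segments tracts, estimates
#' velocity, lineal density, hematocrit and supply rate, and — when a
#' 438 nm channel is present — computes per-tract SO2 from the matched
#' dual-wavelength tract ODs.
#'
#' @param seq [frame_sequence()].
#' @param segment [capillary_segment()].
#' @param calib [calibration_constants()].
#' @param window Velocity window in seconds.
#' @param ... Passed to [segment_tracts()].
#' @return Object of class `capillary_dynamics`: `timestamps`, `velocity`
#'   (um/s), `lineal_density` (RBC/mm), `hematocrit` (%), `supply_rate`
#'   (RBC/s), `so2` (per-tract data.frame or NULL), `capillary_id`.
#' @export
analyze_capillary <- function(seq, segment, calib = calibration_constants(),
                              window = 0.5, ...) {
  sti450 <- build_sti(seq, segment, wavelength = 450)
  seg <- segment_tracts(sti450, ...)
  est <- estimate_velocity(sti450, seg, window = window)
  ld <- lineal_density(seg$mask, sti450$length_um / 1000)
  so2 <- NULL
  has438 <- any(abs(suppressWarnings(
    as.numeric(names(seq$frames_per_wavelength))) - 438) < 0.5)
  if (has438 && any(seg$mask)) {
    sti438 <- build_sti(seq, segment, wavelength = 438)
    so2 <- tract_so2(tract_od(sti438, seg), tract_od(sti450, seg), calib)
  }
  structure(list(timestamps = sti450$timestamps, velocity = est$velocity,
                 lineal_density = ld,
                 hematocrit = hematocrit_from_density(ld),
                 supply_rate = supply_rate(est$velocity, ld), so2 = so2,
                 capillary_id = segment$capillary_id,
                 window_velocity = est$window_velocity,
                 window_mid_s = est$window_mid_s),
            class = "capillary_dynamics")
}

#' @export
print.capillary_dynamics <- function(x, ...) {
  cat(sprintf(
    "<capillary_dynamics> %s: %d frames, median |v| %.0f um/s, median LD %.0f RBC/mm\n",
    x$capillary_id, length(x$timestamps),
    stats::median(abs(x$velocity)), stats::median(x$lineal_density)))
  invisible(x)
}
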