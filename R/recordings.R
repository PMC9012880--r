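#' Timed dual-wavelength frame sequence
#'
#' Container for an intravital video acquisition: per-wavelength stacks of
#' intensity frames (arbitrary linear counts) sharing one time base. The
#' reference acquisition geometry is 696 x 520 pixels, 12-bit depth, 21
#' frames/s, with simultaneous 438 nm (oxygen-dependent) and 450 nm
#' (isosbestic) channels.
#'
#' @param frames_per_wavelength Named list keyed by wavelength in nm (e.g.
#'   `"438"`, `"450"`), each a numeric array `rows x cols x n_frames`.
#' @param timestamps Frame times in seconds, strictly increasing.
#' @param pixel_size Microns per pixel.
#' @param bit_depth Camera bit depth; intensities must lie in
#'   `[0, 2^bit_depth)`.
#' @param fov_id Field-of-view identifier.
#' @param group_label `"control"` or `"FIP"`.
#' @param imaging_period Imaging period 1, 2 or 3.
#' @return Object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames_per_wavelength, timestamps, pixel_size,
                           bit_depth = 12, fov_id = "fov",
                           group_label = c("control", "FIP"),
                           imaging_period = 1L) {
  group_label <- match.arg(group_label)
  if (is.null(names(frames_per_wavelength)) ||
      any(names(frames_per_wavelength) == ""))
    stop("frame_sequence: frames_per_wavelength must be named by wavelength (nm)")
  dims <- lapply(frames_per_wavelength, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("frame_sequence: each stack must be a rows x cols x frames array")
  if (length(unique(lapply(dims, identity))) != 1L)
    stop("frame_sequence: all wavelengths must share the frame shape")
  n <- dims[[1]][3]
  if (length(timestamps) != n)
    stop("frame_sequence: timestamps length must equal frame count")
  if (any(diff(timestamps) <= 0))
    stop("frame_sequence: timestamps must be strictly increasing")
  rng <- range(vapply(frames_per_wavelength, range, numeric(2)))
  if (rng[1] < 0 || rng[2] >= 2^bit_depth)
    stop("frame_sequence: intensities must lie in [0, 2^bit_depth)")
  if (!imaging_period %in% 1:3)
    stop("frame_sequence: imaging_period must be 1, 2 or 3")
  structure(list(frames_per_wavelength = frames_per_wavelength,
                 timestamps = as.numeric(timestamps),
                 pixel_size = pixel_size, bit_depth = bit_depth,
                 fov_id = fov_id, group_label = group_label,
                 imaging_period = as.integer(imaging_period)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames_per_wavelength[[1]])
  cat(sprintf(
    "<frame_sequence> fov %s (%s, period %d): %s nm, %dx%d px, %d frames, %.3f um/px\n",
    x$fov_id, x$group_label, x$imaging_period,
    paste(names(x$frames_per_wavelength), collapse = "/"),
    d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

wavelength_stack <- function(seq, wavelength) {
  key <- as.character(wavelength)
  # tolerate "450" vs "450.0" style keys
  keys <- names(seq$frames_per_wavelength)
  hit <- which(suppressWarnings(abs(as.numeric(keys) - as.numeric(key))) < 0.5)
  if (!length(hit))
    stop("wavelength ", wavelength, " nm not present (have: ",
         paste(keys, collapse = ", "), ")")
  seq$frames_per_wavelength[[hit[1]]]
}

#' Mean frame intensity series
#'
#' Arithmetic mean over all pixels of each frame at one wavelength, the
#' basis of the MFI-derived hemoglobin-content series. Saturated pixels
#' (at or above `2^bit_depth - 1`) are excluded from the mean; their total
#' count is reported via a message when present.
#'
#' @param seq [frame_sequence()].
#' @param wavelength Wavelength in nm (must be present in `seq`).
#' @return Numeric vector, one mean per frame.
#' @export
mean_frame_intensity <- function(seq, wavelength = 450) {
  stopifnot(inherits(seq, "frame_sequence"))
  stack <- wavelength_stack(seq, wavelength)
  sat_level <- 2^seq$bit_depth - 1
  sat <- stack >= sat_level
  n_sat <- sum(sat)
  if (n_sat > 0) {
    message("mean_frame_intensity: excluding ", n_sat, " saturated pixel(s)")
    stack[sat] <- NA_real_
  }
  apply(stack, 3, mean, na.rm = TRUE)
}

#' Continuous-wave spectroscopy recording
#'
#' Wavelength x time matrix of transmitted-light intensities collected
#' from one field of view (450-650 nm band, ~10-11 recordings/s, 2 min).
#'
#' @param wavelengths Wavelength grid in nm, strictly increasing.
#' @param timestamps Acquisition times in seconds, strictly increasing.
#' @param intensities Matrix `length(wavelengths) x length(timestamps)`,
#'   nonnegative.
#' @inheritParams frame_sequence
#' @return Object of class `spectral_recording`.
#' @export
spectral_recording <- function(wavelengths, timestamps, intensities,
                               fov_id = "fov",
                               group_label = c("control", "FIP"),
                               imaging_period = 1L) {
  group_label <- match.arg(group_label)
  if (!is.matrix(intensities) ||
      nrow(intensities) != length(wavelengths) ||
      ncol(intensities) != length(timestamps))
    stop("spectral_recording: intensities must be wavelengths x timestamps")
  if (any(diff(timestamps) <= 0))
    stop("spectral_recording: timestamps must be strictly increasing")
  if (any(diff(wavelengths) <= 0))
    stop("spectral_recording: wavelengths must be strictly increasing")
  if (any(intensities < 0))
    stop("spectral_recording: intensities must be >= 0")
  structure(list(wavelengths = as.numeric(wavelengths),
                 timestamps = as.numeric(timestamps),
                 intensities = intensities, fov_id = fov_id,
                 group_label = group_label,
                 imaging_period = as.integer(imaging_period)),
            class = "spectral_recording")
}

#' @export
print.spectral_recording <- function(x, ...) {
  cat(sprintf(
    "<spectral_recording> fov %s (%s, period %d): %g-%g nm, %d profiles over %.1f s\n",
    x$fov_id, x$group_label, x$imaging_period, min(x$wavelengths),
    max(x$wavelengths), length(x$timestamps), diff(range(x$timestamps))))
  invisible(x)
}

#' Mean isosbestic OD-change series from a spectroscopy recording
#'
#' For each of the six isosbestic wavelengths, intensities within a
#' `bandpass`-wide window are averaged, converted to an OD-change series
#' relative to the first sample, and the six series are averaged without
#' weighting. At isosbestic wavelengths the extinction coefficients of
#' oxy- and deoxyhemoglobin are equal, so the result tracks microvascular
#' hemoglobin content irrespective of saturation; averaging six bands
#' suppresses uncorrelated noise by about `sqrt(6)`.
#'
#' @param rec [spectral_recording()].
#' @param wavelengths Isosbestic set in nm (default
#'   [isosbestic_wavelengths()]).
#' @param bandpass Full bandwidth in nm of each averaging window
#'   (default 2, i.e. lambda +/- 1 nm inclusive).
#' @return [od_time_series()] with `source = "CWS"`.
#' @export
isosbestic_average <- function(rec, wavelengths = isosbestic_wavelengths(),
                               bandpass = 2) {
  stopifnot(inherits(rec, "spectral_recording"))
  half <- bandpass / 2
  sel <- lapply(wavelengths, function(w)
    which(abs(rec$wavelengths - w) <= half + 1e-9))
  missing <- wavelengths[vapply(sel, length, 1L) == 0L]
  if (length(missing))
    stop("isosbestic_average: no spectral coverage at ",
         paste(missing, collapse = ", "), " nm")
  od <- vapply(sel, function(idx) {
    band <- colMeans(rec$intensities[idx, , drop = FALSE])
    if (any(band <= 0))
      stop("isosbestic_average: nonpositive band intensity encountered")
    log10(band[1] / band)
  }, numeric(length(rec$timestamps)))
  od_time_series(rec$timestamps, rowMeans(od), source = "CWS",
                 wavelength_set = wavelengths, fov_id = rec$fov_id)
}

#' Resample a timed series onto a uniform grid
#'
#' Linear interpolation onto a uniform grid running from the first to the
#' last timestamp at the requested rate; no extrapolation is performed.
#' Used to regularize spectroscopy recordings whose acquisition timing
#' jitters around the nominal 10-11 samples/s before Fourier analysis.
#'
#' @param x Timestamps (seconds, strictly increasing) or an
#'   [od_time_series()].
#' @param values Series values (ignored for `od_time_series` input).
#' @param rate Target sampling rate in Hz (default 10.5).
#' @return For numeric input, a list with `timestamps` and `values`; for
#'   `od_time_series` input, a resampled `od_time_series`.
#' @export
resample_uniform <- function(x, values = NULL, rate = 10.5) {
  UseMethod("resample_uniform")
}

#' @export
resample_uniform.default <- function(x, values = NULL, rate = 10.5) {
  timestamps <- as.numeric(x)
  if (length(timestamps) < 2)
    stop("resample_uniform: need at least 2 samples")
  if (any(diff(timestamps) <= 0))
    stop("resample_uniform: timestamps must be strictly increasing")
  if (rate <= 0) stop("resample_uniform: rate must be > 0")
  grid <- seq(timestamps[1], timestamps[length(timestamps)], by = 1 / rate)
  list(timestamps = grid,
       values = stats::approx(timestamps, values, xout = grid)$y)
}

#' @export
resample_uniform.od_time_series <- function(x, values = NULL, rate = 10.5) {
  rs <- resample_uniform(x$timestamps, x$delta_od, rate)
  od_time_series(rs$timestamps, rs$values - rs$values[1], source = x$source,
                 wavelength_set = x$wavelength_set, fov_id = x$fov_id)
}
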