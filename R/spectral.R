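#' One-sided amplitude-squared power spectrum
#'
#' The series mean is removed (no taper, no zero-padding) and the
#' one-sided amplitude spectrum is computed as `A_k = 2|X_k|/N` for
#' interior bins, with the DC and (for even N) Nyquist bins unhalved, so
#' that a sinusoid of amplitude A at a bin frequency has Power exactly
#' `A^2`. Power is the square of the amplitude.
#'
#' @param series [od_time_series()] (or any list with `timestamps` and
#'   `delta_od`) with uniform sampling and at least 64 samples.
#' @param rel_tol Relative tolerance on timestamp uniformity.
#' @return Object of class `power_spectrum`: `frequencies` (Hz), `power`
#'   (amplitude^2), `amplitude`, `series_source`, `fov_id`.
#' @export
power_spectrum <- function(series, rel_tol = 1e-6) {
  tt <- series$timestamps; x <- series$delta_od
  n <- length(x)
  if (n < 64) stop("power_spectrum: need at least 64 samples")
  dtv <- diff(tt)
  dt <- mean(dtv)
  if (max(abs(dtv - dt)) > rel_tol * dt)
    stop("power_spectrum: non-uniform timestamps; resample_uniform() first")
  x <- x - mean(x)
  xf <- stats::fft(x)
  half <- floor(n / 2)
  k <- 0:half
  amp <- Mod(xf[k + 1]) / n
  interior <- k > 0 & !(n %% 2 == 0 & k == half)
  amp[interior] <- 2 * amp[interior]
  structure(list(frequencies = k / (n * dt), power = amp^2,
                 amplitude = amp,
                 series_source = series$source %||% "MFI",
                 fov_id = series$fov_id %||% "fov"),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %s, fov %s: %d bins up to %.3f Hz\n",
              x$series_source, x$fov_id, length(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

#' Peak Power in the vasomotion band
#'
#' Maximum of the Power spectrum over bins with frequency inside the band
#' (inclusive on both edges; default 0.03-0.06 Hz, periods 16-32 s). Ties
#' resolve to the lowest frequency.
#'
#' @param spec [power_spectrum()].
#' @param band Frequency band in Hz.
#' @return Object of class `band_peak`: `peak_power`, `peak_frequency`
#'   (Hz), `peak_period` (s), `band`, `series_source`, `fov_id`.
#' @export
peak_power_in_band <- function(spec, band = c(0.03, 0.06)) {
  stopifnot(inherits(spec, "power_spectrum"))
  sel <- which(spec$frequencies >= band[1] - 1e-12 &
                 spec$frequencies <= band[2] + 1e-12 &
                 spec$frequencies > 0)
  if (!length(sel))
    stop(sprintf(paste0(
      "peak_power_in_band: no frequency bins inside [%g, %g] Hz; ",
      "record at least %.0f s of data"), band[1], band[2],
      ceiling(1 / band[1])))
  i <- sel[which.max(spec$power[sel])]
  structure(list(peak_power = spec$power[i],
                 peak_frequency = spec$frequencies[i],
                 peak_period = 1 / spec$frequencies[i], band = band,
                 series_source = spec$series_source, fov_id = spec$fov_id),
            class = "band_peak")
}

#' @export
print.band_peak <- function(x, ...) {
  cat(sprintf(
    "<band_peak> %s, fov %s: Power %.3g at %.4f Hz (period %.1f s)\n",
    x$series_source, x$fov_id, x$peak_power, x$peak_frequency,
    x$peak_period))
  invisible(x)
}

#' Paired band peaks for one field of view
#'
#' Computes the vasomotion band peak for the video-derived (MFI) and
#' spectroscopy-derived (CWS) OD series of the same field, returning a
#' tidy table for the statistics module. A missing modality yields a
#' partial record with a message.
#'
#' @param mfi_series,cws_series [od_time_series()] objects (either may be
#'   NULL).
#' @param band Frequency band in Hz.
#' @param resample_rate If a series is non-uniform it is first resampled
#'   at this rate (Hz).
#' @return data.frame `fov_id, source, peak_power, peak_freq_hz,
#'   peak_period_s`.
#' @export
band_peak_for_fov <- function(mfi_series = NULL, cws_series = NULL,
                              band = c(0.03, 0.06), resample_rate = 10.5) {
  one <- function(series) {
    if (is.null(series)) return(NULL)
    dtv <- diff(series$timestamps)
    if (max(abs(dtv - mean(dtv))) > 1e-6 * mean(dtv))
      series <- resample_uniform(series, rate = resample_rate)
    bp <- peak_power_in_band(power_spectrum(series), band)
    data.frame(fov_id = bp$fov_id, source = bp$series_source,
               peak_power = bp$peak_power,
               peak_freq_hz = bp$peak_frequency,
               peak_period_s = bp$peak_period, stringsAsFactors = FALSE)
  }
  parts <- list(one(mfi_series), one(cws_series))
  if (any(vapply(parts, is.null, logical(1))))
    message("band_peak_for_fov: only one modality present; partial record")
  out <- do.call(rbind, parts)
  if (is.null(out))
    stop("band_peak_for_fov: no series provided")
  out
}
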