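#' Beer-Lambert optical density
#'
#' OD at an isosbestic wavelength is extinction coefficient x path length x
#' hemoglobin concentration; the transmitted fraction is `10^(-OD)`.
#' All arguments are vectorized and recycled.
#'
#' @param eps Extinction coefficient (per mM per cm).
#' @param path_length Optical path length (cm).
#' @param concentration Hemoglobin concentration (mM).
#' @return Dimensionless optical density `eps * path_length * concentration`.
#' @examples
#' beer_lambert_od(5.3, 0.1, 0.4)          # 0.212
#' 10^-beer_lambert_od(5.3, 0.1, 0.4)      # transmitted fraction
#' @export
beer_lambert_od <- function(eps, path_length, concentration) {
  if (any(eps < 0) || any(path_length < 0) || any(concentration < 0))
    stop("beer_lambert_od: all arguments must be >= 0")
  eps * path_length * concentration
}

#' Hemoglobin extinction coefficient table
#'
#' Returns the packaged table of approximate oxy/deoxyhemoglobin extinction
#' coefficients (per mM per cm) at 438 nm, 450 nm and the six visible-band
#' isosbestic wavelengths, compiled from standard literature values; the
#' file is a synthetic stand-in intended for the forward simulator and
#' unit-consistency checks, not for absolute quantification.
#'
#' @param path Optional path to an alternative CSV with the same columns
#'   (`wavelength_nm, eps_oxy_per_mM_cm, eps_deoxy_per_mM_cm, is_isosbestic`).
#' @return `data.frame` with one row per wavelength.
#' @export
hb_extinction <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hb_extinction_synthetic.csv",
                        package = "capspec", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "eps_oxy_per_mM_cm", "eps_deoxy_per_mM_cm",
            "is_isosbestic")
  if (!all(need %in% names(tab)))
    stop("hb_extinction: table must have columns ", paste(need, collapse = ", "))
  iso <- tab$is_isosbestic
  if (any(tab$eps_oxy_per_mM_cm[iso] != tab$eps_deoxy_per_mM_cm[iso]))
    stop("hb_extinction: isosbestic rows must have equal oxy/deoxy coefficients")
  tab
}

# Interpolate extinction coefficients (per mM per cm) at arbitrary
# wavelengths for a given saturation; constant extrapolation at the ends.
eps_at <- function(wavelength, so2 = 1, table = hb_extinction()) {
  eps <- so2 * table$eps_oxy_per_mM_cm + (1 - so2) * table$eps_deoxy_per_mM_cm
  stats::approx(table$wavelength_nm, eps, xout = wavelength, rule = 2)$y
}

#' Calibration constants for the 438/450 nm OD-ratio oximeter
#'
#' The RBC oxygen saturation estimate is an affine map of the 438/450 nm
#' optical-density ratio between its fully-deoxygenated and
#' fully-oxygenated endpoints. In vivo these endpoints come from a
#' calibration experiment; the defaults here are configurable placeholders
#' used symmetrically by the forward simulator and the analysis.
#'
#' @param ratio_oxy OD ratio at SO2 = 1 (dimensionless, > 0).
#' @param ratio_deoxy OD ratio at SO2 = 0 (dimensionless, > 0).
#' @return Object of class `calibration_constants`.
#' @export
calibration_constants <- function(ratio_oxy = 1.2, ratio_deoxy = 0.6) {
  if (!(ratio_oxy > 0 && ratio_deoxy > 0))
    stop("calibration_constants: both ratios must be > 0")
  if (ratio_oxy == ratio_deoxy)
    stop("calibration_constants: ratio_oxy must differ from ratio_deoxy")
  structure(list(ratio_oxy = ratio_oxy, ratio_deoxy = ratio_deoxy),
            class = "calibration_constants")
}

#' RBC oxygen saturation from the 438/450 nm OD ratio
#'
#' Computes `R = od_438 / od_450` and maps it affinely between the
#' calibration endpoints, clipping to the physical range \[0, 1\].
#' Vectorized over the OD arguments.
#'
#' @param od_438 Optical density at 438 nm (oxygen-dependent wavelength).
#' @param od_450 Optical density at 450 nm (isosbestic); must be > 0.
#' @param calib [calibration_constants()].
#' @return Saturation fraction in \[0, 1\].
#' @export
rbc_so2 <- function(od_438, od_450, calib = calibration_constants()) {
  stopifnot(inherits(calib, "calibration_constants"))
  if (any(!is.finite(od_450)) || any(od_450 <= 0))
    stop("rbc_so2: od_450 must be > 0 (no RBC signal)")
  r <- od_438 / od_450
  so2 <- (r - calib$ratio_deoxy) / (calib$ratio_oxy - calib$ratio_deoxy)
  pmin(1, pmax(0, so2))
}

#' Optical-density time series (change relative to the first sample)
#'
#' Container for `delta_od(t) = log10(I(t1) / I(t))`, derived either from
#' mean frame intensity (`source = "MFI"`) or continuous-wave spectroscopy
#' (`source = "CWS"`). By construction the first sample is 0; an intensity
#' decrease (more hemoglobin in the light path) gives a positive value.
#'
#' @param timestamps Seconds from acquisition start, strictly increasing.
#' @param delta_od Dimensionless OD change, finite, first element 0.
#' @param source `"MFI"` or `"CWS"`.
#' @param wavelength_set Wavelengths (nm) entering the series.
#' @param fov_id Field-of-view identifier.
#' @return Object of class `od_time_series`.
#' @export
od_time_series <- function(timestamps, delta_od, source = c("MFI", "CWS"),
                           wavelength_set = numeric(), fov_id = "fov") {
  source <- match.arg(source)
  timestamps <- as.numeric(timestamps)
  delta_od <- as.numeric(delta_od)
  if (length(timestamps) != length(delta_od))
    stop("od_time_series: timestamps and delta_od lengths differ")
  if (any(diff(timestamps) <= 0))
    stop("od_time_series: timestamps must be strictly increasing")
  if (any(!is.finite(delta_od)))
    stop("od_time_series: delta_od must be finite")
  if (abs(delta_od[1]) > 1e-12)
    stop("od_time_series: delta_od must be 0 at the first timestamp")
  structure(list(timestamps = timestamps, delta_od = delta_od,
                 source = source, wavelength_set = wavelength_set,
                 fov_id = fov_id),
            class = "od_time_series")
}

#' @export
print.od_time_series <- function(x, ...) {
  cat(sprintf("<od_time_series> %s, fov %s: %d samples over %.1f s\n",
              x$source, x$fov_id, length(x$timestamps),
              diff(range(x$timestamps))))
  invisible(x)
}

#' OD change series from a transmitted-intensity series
#'
#' `delta_od(t) = log10(I(t1) / I(t))`: the change in optical density
#' relative to the first time point. Rising hemoglobin content attenuates
#' transmitted light and therefore raises `delta_od`.
#'
#' @param intensity Mean transmitted intensities (arbitrary linear counts,
#'   all > 0).
#' @param timestamps Sample times in seconds; defaults to 0-based indices.
#' @inheritParams od_time_series
#' @return [od_time_series()].
#' @export
delta_od_series <- function(intensity, timestamps = seq_along(intensity) - 1,
                            source = c("MFI", "CWS"),
                            wavelength_set = numeric(), fov_id = "fov") {
  bad <- which(!is.finite(intensity) | intensity <= 0)
  if (length(bad))
    stop("delta_od_series: nonpositive intensity at index ", bad[1])
  od_time_series(timestamps, log10(intensity[1] / intensity),
                 source = source, wavelength_set = wavelength_set,
                 fov_id = fov_id)
}
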