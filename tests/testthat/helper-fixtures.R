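# Shared builders for small in-code fixtures.

# Horizontal centerline from x0 to x1 at row y (0-based pixel coords).
hline <- function(x0, x1, y) cbind(c(x0, x1), c(y, y))

# Small-frame simulation config used throughout the video tests: one
# capillary across a 24 x 118 px frame, 450 nm only unless dual = TRUE.
quick_cfg <- function(programs, duration = 10, seed = 1, dual = FALSE,
                      ...) {
  simulation_config(frame_shape = c(24, 118), duration = duration,
                    seed = seed,
                    wavelengths = if (dual) c(438, 450) else 450,
                    capillary_programs = programs, ...)
}

quick_centerline <- function() hline(4, 112, 11.5)

# Hand-built space-time image (position x time) for estimator tests.
make_sti <- function(m, position_step = 0.6466, time_step = 1 / 21) {
  structure(list(matrix = m, position_step = position_step,
                 time_step = time_step,
                 timestamps = (seq_len(ncol(m)) - 1) * time_step,
                 wavelength = 450, capillary_id = "synthetic",
                 length_um = nrow(m) * position_step),
            class = "space_time_image")
}

# STI with dark diagonal stripes of the given slope (rows per column),
# stripe width `width` rows out of a `period`-row cycle.
stripe_sti <- function(nr = 80, nc = 63, slope = 1, width = 4,
                       period = 12, gap_val = 1000, tract_val = 500) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  dark <- ((rr - round(slope * cc)) %% period) < width
  make_sti(ifelse(dark, tract_val, gap_val))
}

# Uniform-value frame sequence.
uniform_seq <- function(value, nr = 20, nc = 30, n = 15,
                        wavelengths = "450") {
  stacks <- lapply(wavelengths, function(w) array(value, c(nr, nc, n)))
  names(stacks) <- wavelengths
  frame_sequence(stacks, (seq_len(n) - 1) / 21, pixel_size = 0.6466)
}

# Spectral recording whose six isosbestic bands carry prescribed OD-change
# series (list of numeric vectors, one per wavelength, first element 0).
iso_recording <- function(od_by_band, timestamps, i0 = 1000) {
  wl <- isosbestic_wavelengths()
  intens <- do.call(rbind, lapply(seq_along(wl), function(i)
    i0 * 10^(-od_by_band[[i]])))
  spectral_recording(wl, timestamps, intens)
}
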