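#' Classify capillary flow state over a 30-s window
#'
#' A capillary is `stopped` if its velocity is 0 throughout the window;
#' `intermittent` if any maximal zero-velocity run strictly exceeds 3 s,
#' or if flow reverses (a run of velocity opposite in sign to the
#' dominant direction sustained for at least `reversal_min` seconds);
#' otherwise `continuous`. Run durations are measured as number of
#' samples times the sampling interval; gaps in coverage break runs.
#'
#' @param dynamics [analyze_capillary()] output, or any list with
#'   `timestamps` and `velocity`.
#' @param window_start Window start in seconds.
#' @param window_length Window length in seconds (default 30).
#' @param stop_run_s Stop-run threshold in seconds (strict inequality;
#'   default 3).
#' @param reversal_min Minimum sustained reversal duration in seconds.
#' @return Object of class `flow_state`: `value`, `window_start`,
#'   `window_length`, `capillary_id`.
#' @export
classify_flow <- function(dynamics, window_start = 0, window_length = 30,
                          stop_run_s = 3, reversal_min = 0.5) {
  tt <- dynamics$timestamps; v <- dynamics$velocity
  dt <- stats::median(diff(tt))
  inside <- tt >= window_start - 1e-9 &
    tt <= window_start + window_length + 1e-9
  if (!any(inside) ||
      tt[1] > window_start + 1e-9 ||
      tt[length(tt)] < window_start + window_length - dt - 1e-9)
    stop("classify_flow: dynamics do not cover [", window_start, ", ",
         window_start + window_length, "] s")
  v <- v[inside]
  value <- if (all(v == 0)) {
    "stopped"
  } else {
    r <- rle(v == 0)
    max_stop <- if (any(r$values)) max(r$lengths[r$values]) * dt else 0
    dom <- sign(sum(sign(v)))
    rs <- rle(as.integer(sign(v)))
    rev_run <- if (dom != 0 && any(rs$values == -dom))
      max(rs$lengths[rs$values == -dom]) * dt else 0
    both_dirs <- dom == 0 && any(v > 0) && any(v < 0)
    if (max_stop > stop_run_s + 1e-9 ||
        rev_run >= reversal_min - 1e-9 || both_dirs)
      "intermittent" else "continuous"
  }
  structure(list(value = value, window_start = window_start,
                 window_length = window_length,
                 capillary_id = dynamics$capillary_id),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> %s: %s over [%g, %g] s\n",
              x$capillary_id %||% "?", x$value, x$window_start,
              x$window_start + x$window_length))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Functional capillary density from line-crossing counts
#'
#' Perfused capillaries are counted where they cross three horizontal test
#' lines (placed at 1/4, 1/2 and 3/4 of the field height); FCD is total
#' crossings divided by total test-line length. A capillary crossing two
#' lines contributes two crossings (crossings, not unique capillaries).
#'
#' @param crossings Total crossing count over the three lines.
#' @param fov_width Field-of-view width in um (length of each test line;
#'   default 450 um).
#' @param n_lines Number of test lines (default 3).
#' @return Capillaries per mm.
#' @export
functional_capillary_density <- function(crossings, fov_width = 450,
                                         n_lines = 3) {
  if (fov_width <= 0)
    stop("functional_capillary_density: fov_width must be > 0")
  crossings / (n_lines * fov_width / 1000)
}

#' Count test-line crossings of capillary centerlines
#'
#' Counts, for each capillary segment, which of the three horizontal test
#' lines (at 1/4, 1/2, 3/4 of the frame height, in pixel rows) its
#' centerline crosses; each (capillary, line) pair counts at most once.
#'
#' @param segments List of [capillary_segment()].
#' @param frame_shape `c(rows, cols)` of the field of view in pixels.
#' @return Integer total crossing count.
#' @export
count_line_crossings <- function(segments, frame_shape) {
  lines_y <- (frame_shape[1] - 1) * c(0.25, 0.5, 0.75)
  sum(vapply(segments, function(seg) {
    y <- seg$points[, 2]
    sum(vapply(lines_y, function(ly) {
      any(diff(sign(y - ly)) != 0) || any(y == ly)
    }, logical(1)))
  }, numeric(1)))
}

#' Field-of-view perfusion metrics
#'
#' Classifies every capillary of a field over one 30-s window and computes
#' functional capillary density from centerline test-line crossings of the
#' capillaries that are not completely stopped.
#'
#' @param dynamics_list List of [analyze_capillary()] outputs.
#' @param segments Matching list of [capillary_segment()].
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param pixel_size um per pixel (to express the line length in um).
#' @param window_start,window_length Classification window (s).
#' @param fov_id,group_label,imaging_period Metadata carried through.
#' @return One-row data.frame: `fov_id, imaging_period, group_label,
#'   fcd_per_mm, n_continuous, n_intermittent, n_stopped`.
#' @export
fov_metrics <- function(dynamics_list, segments, frame_shape,
                        pixel_size = 0.6466, window_start = 0,
                        window_length = 30, fov_id = "fov",
                        group_label = "control", imaging_period = 1L) {
  states <- vapply(dynamics_list, function(d)
    classify_flow(d, window_start, window_length)$value, character(1))
  perfused <- segments[states != "stopped"]
  crossings <- count_line_crossings(perfused, frame_shape)
  fcd <- functional_capillary_density(
    crossings, fov_width = (frame_shape[2] - 1) * pixel_size)
  data.frame(fov_id = fov_id, imaging_period = imaging_period,
             group_label = group_label, fcd_per_mm = fcd,
             n_continuous = sum(states == "continuous"),
             n_intermittent = sum(states == "intermittent"),
             n_stopped = sum(states == "stopped"),
             stringsAsFactors = FALSE)
}
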