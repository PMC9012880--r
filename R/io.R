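# --- minimal 16-bit grayscale PNG writer -------------------------------
# The png package reads 16-bit PNGs but writes only 8-bit; 12-bit camera
# counts need the 16-bit container to round-trip losslessly, so the
# encoder (IHDR/IDAT/IEND, filter 0, zlib via memCompress) lives here.

png_crc_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    crc <- n
    for (k in 1:8)
      crc <- if (bitwAnd(crc, 1L))
        bitwXor(-306674912L, bitwShiftR(crc, 1L)) else bitwShiftR(crc, 1L)
    tab[n + 1] <- crc
  }
  tab
})

png_crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(png_crc_table[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  bitwXor(crc, -1L)
}

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  crc <- png_crc32(payload)
  c(writeBin(length(data), raw(), size = 4, endian = "big"), payload,
    writeBin(crc, raw(), size = 4, endian = "big"))
}

# Write an integer matrix of counts in [0, 65535] as 16-bit gray PNG.
write_png16 <- function(m, path) {
  nr <- nrow(m); nc <- ncol(m)
  v <- as.integer(round(m))
  if (any(v < 0L | v > 65535L))
    stop("write_png16: counts must lie in [0, 65535]")
  dim(v) <- c(nr, nc)
  sl <- matrix(0L, 1L + 2L * nc, nr)          # one scanline per column
  sl[2L * seq_len(nc), ] <- t(v %/% 256L)
  sl[2L * seq_len(nc) + 1L, ] <- t(v %% 256L)
  ihdr <- c(writeBin(nc, raw(), size = 4, endian = "big"),
            writeBin(nr, raw(), size = 4, endian = "big"),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))   # 16-bit, grayscale
  # memCompress "gzip" emits the RFC 1950 zlib stream PNG requires
  idat <- memCompress(as.raw(as.vector(sl)), type = "gzip")
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Write and read per-frame PNG directories
#'
#' Frames are stored one 16-bit grayscale PNG per frame per wavelength
#' with the filename pattern `<fov>_<wavelength>nm_<frameindex>.png`
#' (0-based, zero-padded index). Counts are stored as raw values in the
#' 16-bit container, so 12-bit data round-trips exactly; reading accepts
#' both 8- and 16-bit grayscale PNGs (values are rescaled from the
#' \[0, 1\] range `png::readPNG` returns).
#'
#' @param seq [frame_sequence()].
#' @param dir Output directory (created if absent).
#' @return `write_frame_dir` invisibly returns the written paths;
#'   `read_frame_dir` returns a [frame_sequence()].
#' @export
write_frame_dir <- function(seq, dir) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (wl in names(seq$frames_per_wavelength)) {
    stack <- seq$frames_per_wavelength[[wl]]
    for (j in seq_len(dim(stack)[3])) {
      p <- file.path(dir, sprintf("%s_%snm_%05d.png", seq$fov_id, wl, j - 1))
      write_png16(stack[, , j], p)
      paths <- c(paths, p)
    }
  }
  meta <- list(timestamps = seq$timestamps, pixel_size = seq$pixel_size,
               bit_depth = seq$bit_depth, fov_id = seq$fov_id,
               group_label = seq$group_label,
               imaging_period = seq$imaging_period)
  jsonlite::write_json(meta, file.path(dir, paste0(seq$fov_id, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_frame_dir
#' @param fov_id Field-of-view id of the files to read.
#' @export
read_frame_dir <- function(dir, fov_id) {
  meta_path <- file.path(dir, paste0(fov_id, "_meta.json"))
  if (!file.exists(meta_path)) stop("read_frame_dir: missing ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- list.files(dir, pattern = paste0("^", fov_id, "_\\d+(\\.\\d+)?nm_\\d+\\.png$"))
  if (!length(files)) stop("read_frame_dir: no frames for fov ", fov_id)
  wl <- sub(paste0("^", fov_id, "_(.*)nm_\\d+\\.png$"), "\\1", files)
  stacks <- lapply(split(files, wl), function(fs) {
    fs <- fs[order(fs)]
    mats <- lapply(fs, function(f)
      round(png::readPNG(file.path(dir, f)) * 65535))
    array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  })
  frame_sequence(stacks, meta$timestamps, meta$pixel_size, meta$bit_depth,
                 meta$fov_id, meta$group_label, meta$imaging_period)
}

#' Write and read multi-page TIFF stacks
#'
#' One 16-bit multi-page TIFF per wavelength, named
#' `<fov>_<wavelength>nm.tif`, plus the same JSON sidecar as
#' [write_frame_dir()].
#'
#' @inheritParams write_frame_dir
#' @export
write_frame_tiff <- function(seq, dir) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (wl in names(seq$frames_per_wavelength)) {
    stack <- seq$frames_per_wavelength[[wl]]
    pages <- lapply(seq_len(dim(stack)[3]), function(j) stack[, , j] / 65535)
    p <- file.path(dir, sprintf("%s_%snm.tif", seq$fov_id, wl))
    tiff::writeTIFF(pages, p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  meta <- list(timestamps = seq$timestamps, pixel_size = seq$pixel_size,
               bit_depth = seq$bit_depth, fov_id = seq$fov_id,
               group_label = seq$group_label,
               imaging_period = seq$imaging_period)
  jsonlite::write_json(meta, file.path(dir, paste0(seq$fov_id, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(dir, fov_id) {
  meta_path <- file.path(dir, paste0(fov_id, "_meta.json"))
  if (!file.exists(meta_path)) stop("read_frame_tiff: missing ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- list.files(dir, pattern = paste0("^", fov_id, "_\\d+(\\.\\d+)?nm\\.tif$"))
  wl <- sub(paste0("^", fov_id, "_(.*)nm\\.tif$"), "\\1", files)
  stacks <- lapply(seq_along(files), function(i) {
    pages <- tiff::readTIFF(file.path(dir, files[i]), all = TRUE)
    array(unlist(lapply(pages, function(m) round(m * 65535))),
          dim = c(dim(pages[[1]]), length(pages)))
  })
  names(stacks) <- wl
  frame_sequence(stacks, meta$timestamps, meta$pixel_size, meta$bit_depth,
                 meta$fov_id, meta$group_label, meta$imaging_period)
}

#' Write and read spectroscopy CSV
#'
#' CSV with first column `time_s` and one column per wavelength, named by
#' the wavelength in nm; one row per acquisition.
#'
#' @param rec [spectral_recording()].
#' @param path CSV path.
#' @export
write_spectral_csv <- function(rec, path) {
  stopifnot(inherits(rec, "spectral_recording"))
  df <- data.frame(time_s = rec$timestamps, t(rec$intensities),
                   check.names = FALSE)
  names(df) <- c("time_s", format(rec$wavelengths, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectral_csv
#' @param ... Metadata passed to [spectral_recording()] (`fov_id`,
#'   `group_label`, `imaging_period`).
#' @export
read_spectral_csv <- function(path, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s")
    stop("read_spectral_csv: first column must be time_s")
  wl <- as.numeric(names(df)[-1])
  if (any(is.na(wl)))
    stop("read_spectral_csv: non-numeric wavelength column names")
  intens <- t(as.matrix(df[, -1]))
  dimnames(intens) <- NULL
  spectral_recording(wl, df$time_s, intens, ...)
}

#' Write and read capillary centerline JSON
#'
#' One JSON file per field of view: a list of
#' `{capillary_id, points: [[x, y], ...]}` in 0-based pixel coordinates,
#' arteriolar end first.
#'
#' @param segments List of [capillary_segment()].
#' @param path JSON path.
#' @export
write_centerlines_json <- function(segments, path) {
  payload <- lapply(segments, function(s)
    list(capillary_id = s$capillary_id,
         points = lapply(seq_len(nrow(s$points)), function(i)
           unname(s$points[i, ]))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centerlines_json
#' @param fov_id Field-of-view id attached to the segments.
#' @export
read_centerlines_json <- function(path, fov_id = "fov") {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(e) {
    pts <- do.call(rbind, lapply(e$points, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    capillary_segment(e$capillary_id, pts, fov_id = fov_id)
  })
}

#' Write analysis outputs as CSV
#'
#' Standard CSV writers: the OD series
#' (`time_s, delta_od, source, fov_id`), per-capillary dynamics
#' (`time_s, velocity_um_s, lineal_density_rbc_mm, hematocrit_pct,
#' supply_rate_rbc_s`), tract SO2 (`tract_id, time_s, so2`), per-FOV
#' metrics, band peaks, and the Power heat-map matrix.
#'
#' @param x Object to write.
#' @param path CSV path.
#' @name output_csv
NULL

#' @rdname output_csv
#' @export
write_od_csv <- function(x, path) {
  stopifnot(inherits(x, "od_time_series"))
  utils::write.csv(data.frame(time_s = x$timestamps, delta_od = x$delta_od,
                              source = x$source, fov_id = x$fov_id),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname output_csv
#' @export
write_dynamics_csv <- function(x, path) {
  stopifnot(inherits(x, "capillary_dynamics"))
  utils::write.csv(data.frame(time_s = x$timestamps,
                              velocity_um_s = x$velocity,
                              lineal_density_rbc_mm = x$lineal_density,
                              hematocrit_pct = x$hematocrit,
                              supply_rate_rbc_s = x$supply_rate),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname output_csv
#' @export
write_tract_so2_csv <- function(x, path) {
  stopifnot(inherits(x, "capillary_dynamics"))
  so2 <- x$so2
  if (is.null(so2)) so2 <- data.frame(tract_id = integer(),
                                      t_mid_s = numeric(), so2 = numeric())
  utils::write.csv(data.frame(tract_id = so2$tract_id,
                              time_s = so2$t_mid_s, so2 = so2$so2),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname output_csv
#' @export
write_heatmap_csv <- function(x, path) {
  df <- data.frame(animal_id = attr(x, "animal_id"),
                   fov_id = rownames(x), as.data.frame(unclass(x)),
                   row.names = NULL, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an ANOVA result as JSON
#'
#' JSON object with `effects`, `posthoc`, `cell_summary` and (when given)
#' `excluded_fovs`.
#'
#' @param result [two_way_anova()] output.
#' @param path JSON path.
#' @param excluded_fovs Optional character vector of excluded fields.
#' @export
write_anova_json <- function(result, path, excluded_fovs = character()) {
  stopifnot(inherits(result, "anova_result"))
  jsonlite::write_json(list(effects = result$effects,
                            posthoc = result$posthoc,
                            cell_summary = result$cell_summary,
                            excluded_fovs = excluded_fovs),
                       path, digits = NA)
  invisible(path)
}
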