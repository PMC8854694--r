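# Readers and writers for the package's on-disk formats.
#
# Conventions: coordinates are micrometres internally; CSV headers carry
# units (`x_um`, `t_min`); pixel-unit inputs require an explicit pixel size
# so units are never mixed silently. All writes are atomic
# (write-to-temporary, then rename).

track_csv_columns <- c("embryo_id", "track_id", "role", "frame", "t_min",
                       "x_um", "y_um", "centre_x_um", "centre_y_um")

#' Read a track table from CSV
#'
#' Reads the canonical track schema, or a tracking-export-style CSV mapped
#' onto it via `mapping`. Validates that every (embryo, track, frame) is
#' unique, frames are contiguous within each track, and the per-frame
#' embryonic-region centre is present. If coordinates are in pixels,
#' supply `pixel_size_um` to convert positions and centres to micrometres.
#'
#' @param path CSV file path.
#' @param mapping Optional named character vector mapping file columns to
#'   canonical names, e.g. `c(TRACK_ID = "track_id", POSITION_X = "x_um")`.
#' @param pixel_size_um If given, x/y/centre columns are multiplied by this
#'   factor (they are assumed to be in pixels).
#' @return A validated track tibble.
#' @export
read_track_csv <- function(path, mapping = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop_bad_arg(sprintf("file '%s' does not exist", path))
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(mapping)) {
    for (from in names(mapping)) {
      if (!from %in% names(tb)) {
        stop_bad_arg(sprintf("mapped column '%s' not present in file", from))
      }
      names(tb)[names(tb) == from] <- mapping[[from]]
    }
  }
  missing_cols <- setdiff(setdiff(track_csv_columns, "t_min"), names(tb))
  if (length(missing_cols) > 0) {
    stop_bad_arg(paste0("track CSV lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!"t_min" %in% names(tb)) tb$t_min <- NA_real_
  if (!is.null(pixel_size_um)) {
    check_number(pixel_size_um, "pixel_size_um", 1e-12)
    for (col in c("x_um", "y_um", "centre_x_um", "centre_y_um")) {
      tb[[col]] <- tb[[col]] * pixel_size_um
    }
  }
  dup <- duplicated(tb[, c("embryo_id", "track_id", "frame")])
  if (any(dup)) {
    bad <- tb[dup, , drop = FALSE][1, ]
    stop_bad_arg(sprintf("duplicate (track_id = '%s', frame = %d) row",
                         bad$track_id, bad$frame))
  }
  for (id in unique(tb$track_id)) {
    fr <- sort(tb$frame[tb$track_id == id])
    if (length(fr) > 1 && any(diff(fr) != 1)) {
      stop_bad_arg(sprintf("track '%s' has non-contiguous frames", id))
    }
  }
  bad_centre <- !is.finite(tb$centre_x_um) | !is.finite(tb$centre_y_um)
  if (any(bad_centre)) {
    stop_bad_arg(sprintf(
      "embryonic-region centre missing for frame(s): %s",
      paste(sort(unique(tb$frame[bad_centre])), collapse = ", ")
    ))
  }
  tb
}

#' Write a track table to CSV (atomically)
#'
#' @param tracks Track tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_track_csv <- function(tracks, path) {
  invisible(write_csv_atomic(tracks, path))
}

#' Read a lifetime image from TIFF
#'
#' Supports two dialects: floating-point TIFFs whose values are lifetimes
#' in ns, and integer TIFFs storing grey levels at a fixed lifetime per
#' level (the export convention is 0.01 ns per grey level). The dialect is
#' detected from the file: integer storage is rescaled by
#' `grey_level_scale`, float storage is taken as ns. Zero grey levels are
#' treated as undefined pixels.
#'
#' @param path TIFF file path.
#' @param grey_level_scale ns per grey level for integer TIFFs.
#' @return A `lifetime_image` (intensity is set to 1 where defined).
#' @export
read_lifetime_tiff <- function(path, grey_level_scale = 0.01) {
  if (!file.exists(path)) stop_bad_arg(sprintf("file '%s' does not exist", path))
  as_norm <- tiff::readTIFF(path)
  as_is <- tiff::readTIFF(path, as.is = TRUE)
  if (isTRUE(all.equal(as_norm, as_is, tolerance = 1e-12))) {
    tau <- as_is                       # float storage: values already ns
  } else {
    tau <- as_is * grey_level_scale    # integer grey levels
  }
  tau[tau <= 0] <- NA_real_
  structure(
    list(tau_ns = tau, intensity = (!is.na(tau)) * 1,
         pixel_size_nm = NA_real_, estimator = "phase"),
    class = "lifetime_image"
  )
}

#' Write a lifetime image as a 16-bit integer TIFF
#'
#' Stores grey levels at `grey_level_scale` ns per level (default 0.01,
#' i.e. 4.83 ns is stored as 483). Undefined pixels are stored as 0.
#'
#' @param lt A `lifetime_image`.
#' @param path Output path.
#' @param grey_level_scale ns per grey level.
#' @return The path, invisibly.
#' @export
write_lifetime_tiff <- function(lt, path, grey_level_scale = 0.01) {
  stopifnot(inherits(lt, "lifetime_image"))
  levels <- round(lt$tau_ns / grey_level_scale)
  levels[is.na(levels)] <- 0
  if (any(levels > 65535)) {
    stop_bad_arg("lifetime exceeds the 16-bit grey-level range at this scale")
  }
  atomic_write(path, function(tmp) {
    tiff::writeTIFF(levels / 65535, tmp, bits.per.sample = 16L)
  })
  invisible(path)
}

#' Write a FLIM decay stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are time bins (16-bit counts); the sidecar records
#' `rep_rate_hz`, `n_bins` and `pixel_size_nm`.
#'
#' @param stack A [flim_stack()].
#' @param tiff_path,json_path Output paths.
#' @return `tiff_path`, invisibly.
#' @export
write_flim_stack <- function(stack, tiff_path, json_path) {
  stopifnot(inherits(stack, "flim_stack"))
  if (max(stack$decay) > 65535) {
    stop_bad_arg("counts exceed the 16-bit range; cannot store this stack")
  }
  nb <- stack$n_bins
  pages <- lapply(seq_len(nb), function(k) stack$decay[, , k] / 65535)
  atomic_write(tiff_path, function(tmp) {
    tiff::writeTIFF(pages, tmp, bits.per.sample = 16L)
  })
  write_json_atomic(
    list(rep_rate_hz = stack$rep_rate, n_bins = nb,
         pixel_size_nm = stack$pixel_size_nm),
    json_path
  )
  invisible(tiff_path)
}

#' Read a FLIM decay stack written by [write_flim_stack()]
#'
#' @param tiff_path Multi-page TIFF of time-bin count images.
#' @param json_path JSON sidecar with `rep_rate_hz`, `n_bins`,
#'   `pixel_size_nm`.
#' @return A [flim_stack()].
#' @export
read_flim_stack <- function(tiff_path, json_path) {
  for (p in c(tiff_path, json_path)) {
    if (!file.exists(p)) stop_bad_arg(sprintf("file '%s' does not exist", p))
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = TRUE)
  if (length(pages) != meta$n_bins) {
    stop_bad_arg(sprintf("sidecar says %d bins but TIFF has %d pages",
                         meta$n_bins, length(pages)))
  }
  decay <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) decay[, , k] <- pages[[k]]
  flim_stack(decay, rep_rate = meta$rep_rate_hz,
             pixel_size_nm = meta$pixel_size_nm)
}

#' Read a named set of polygon ROIs from JSON
#'
#' The format is an object mapping ROI names to arrays of `[x, y]` pixel
#' coordinates: `{"epiblast": [[1, 2], [10, 2], [10, 12]], ...}`.
#'
#' @param path JSON file path.
#' @return Named list of data.frames with `x`, `y`.
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop_bad_arg(sprintf("file '%s' does not exist", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) {
    m <- as.matrix(m)
    data.frame(x = m[, 1], y = m[, 2])
  })
}

#' Write a named set of polygon ROIs to JSON
#'
#' @param rois Named list of polygons (data.frames with `x`, `y`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_roi_json <- function(rois, path) {
  payload <- lapply(rois, function(p) unname(as.matrix(p[, c("x", "y")])))
  invisible(write_json_atomic(payload, path))
}

# Standard run report written next to every CLI output.
write_run_report <- function(path, stage, config, seed = NULL,
                             exclusions = NULL) {
  write_json_atomic(
    list(
      package = "epiquant",
      version = as.character(packageVersion("epiquant")),
      stage = stage,
      seed = seed,
      config = config,
      exclusions = exclusions,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    path
  )
}
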