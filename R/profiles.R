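#' Sample an intensity profile along a freehand path
#'
#' Reproduces a width-averaged line profile: the path (an ordered polyline
#' in 0-based pixel coordinates) is resampled at equal arc-length steps;
#' at each sample the intensity is the mean of `width` bilinear samples
#' spaced one pixel apart along the local normal (the line tool used a
#' width of 3). Distances along the path are also expressed as percent of
#' total path length, 100% being the far end of the apical domain, so that
#' profiles from cells with different apical domain sizes are comparable.
#'
#' @param image Numeric matrix (image, `[row, col]`, 0-based coordinates).
#' @param path Data.frame with `x`, `y`: ordered polyline (>= 2 points).
#' @param width Odd integer >= 1: number of perpendicular samples averaged.
#' @param step Arc-length sampling step in pixels (default 1).
#' @return A tibble with `s_px` (arc length), `percent` (0-100) and
#'   `intensity`.
#' @export
sample_profile <- function(image, path, width = 3L, step = 1) {
  width <- as.integer(width)
  if (width < 1 || width %% 2 == 0) stop_bad_arg("`width` must be odd and >= 1")
  check_number(step, "step", 1e-9)
  rs <- resample_polyline(path, step = step)
  n <- nrow(rs)
  # Local tangent by central differences (one-sided at the ends).
  tx <- c(rs$x[2] - rs$x[1], rs$x[-(1:2)] - rs$x[seq_len(n - 2)],
          rs$x[n] - rs$x[n - 1])
  ty <- c(rs$y[2] - rs$y[1], rs$y[-(1:2)] - rs$y[seq_len(n - 2)],
          rs$y[n] - rs$y[n - 1])
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl; ty <- ty / tl
  nxv <- -ty; nyv <- tx
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2)
  acc <- matrix(0, n, length(offsets))
  for (j in seq_along(offsets)) {
    acc[, j] <- bilinear(image, rs$x + offsets[j] * nxv, rs$y + offsets[j] * nyv)
  }
  total <- rs$s[n]
  tibble(
    s_px = rs$s,
    percent = rs$s / total * 100,
    intensity = rowMeans(acc)
  )
}

#' Normalise a profile by the mean intensity in the cell's nucleus
#'
#' Depth-dependent signal attenuation makes raw intensities incomparable
#' between cells at different imaging depths; dividing by the mean
#' intensity over the same cell's nucleus cancels the multiplicative
#' attenuation. The normalised profile is invariant to global intensity
#' scaling of the image.
#'
#' @param profile Tibble from [sample_profile()].
#' @param image The image the profile was sampled from.
#' @param nucleus Polygon (data.frame `x`, `y`, 0-based pixel coordinates)
#'   outlining the nucleus.
#' @return The profile with columns `normalizer` (nuclear mean) and
#'   `normalized` added.
#' @export
normalize_profile <- function(profile, image, nucleus) {
  mask <- polygon_mask(nucleus, nrow(image), ncol(image))
  if (!any(mask)) stop_bad_arg("nucleus mask contains no pixels")
  nuc_mean <- mean(image[mask])
  if (!is.finite(nuc_mean) || nuc_mean <= 0) {
    stop_bad_arg("nuclear mean intensity must be positive")
  }
  profile$normalizer <- nuc_mean
  profile$normalized <- profile$intensity / nuc_mean
  profile
}

#' Mean and SD intensity profile across several junction paths
#'
#' Used for apical-basal profiles across multiple cell-cell junctions:
#' each path is sampled, rescaled to percent distance, interpolated onto a
#' common percent grid, and summarised per position as mean with sample
#' SD across paths.
#'
#' @param image Numeric matrix.
#' @param paths List of >= 1 polylines (data.frames `x`, `y`).
#' @param width Profile width (see [sample_profile()]).
#' @param n_out Number of positions on the common percent grid.
#' @return A tibble with `percent`, `mean`, `sd` (NA when only one path)
#'   and `n_paths`.
#' @export
junction_axis_profile <- function(image, paths, width = 3L, n_out = 51L) {
  if (length(paths) < 1) stop_bad_arg("need at least one path")
  grid <- seq(0, 100, length.out = n_out)
  mat <- vapply(paths, function(p) {
    pr <- sample_profile(image, p, width = width)
    approx(pr$percent, pr$intensity, xout = grid, ties = "ordered")$y
  }, numeric(n_out))
  mat <- matrix(mat, nrow = n_out)
  if (length(paths) == 1) {
    inform("single path: SD undefined, reported as NA")
  }
  tibble(
    percent = grid,
    mean = rowMeans(mat),
    sd = if (length(paths) > 1) apply(mat, 1, sd) else NA_real_,
    n_paths = length(paths)
  )
}

#' LOWESS fit with bootstrap confidence band over pooled profiles
#'
#' Pools normalised profile points from many cells (the reference design
#' is 3 embryos per genotype with 5 cells per embryo), fits a locally
#' weighted regression of normalised intensity on percent position, and
#' derives a pointwise 95% confidence band by bootstrap. The resampling
#' unit is the cell: cells are resampled with replacement within each
#' embryo so the between-embryo structure of the design is respected.
#'
#' @param profiles Tibble with columns `percent`, `normalized`, `cell`
#'   (cell identifier, the bootstrap unit) and optionally `embryo`
#'   (stratum).
#' @param fraction LOWESS smoother span in (0, 1\] (default 0.3).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param grid Percent positions at which the fit is evaluated.
#' @param conf Confidence level for the percentile band.
#' @return An object of class `profile_fit` with `curve` (tibble:
#'   `percent`, `fit`, `lower`, `upper`), `fraction`, `n_boot`, `n_cells`,
#'   `n_points`. `tidy()` returns the curve.
#' @export
fit_lowess_band <- function(profiles, fraction = 0.3, n_boot = 1000L,
                            seed = 1L, grid = seq(0, 100, by = 2),
                            conf = 0.95) {
  if (!all(c("percent", "normalized", "cell") %in% names(profiles))) {
    stop_bad_arg("`profiles` needs columns percent, normalized, cell")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop_bad_arg("`fraction` must be in (0, 1]")
  }
  if (nrow(profiles) < 10) stop_bad_arg("need at least 10 pooled points")
  if (!"embryo" %in% names(profiles)) profiles$embryo <- "all"

  fit_on <- function(df) {
    lw <- lowess(df$percent, df$normalized, f = fraction)
    approx(lw$x, lw$y, xout = grid, rule = 2, ties = "ordered")$y
  }
  fit <- fit_on(profiles)

  cells <- dplyr::distinct(profiles, .data$embryo, .data$cell)
  set.seed(as.integer(seed))
  boots <- matrix(NA_real_, length(grid), n_boot)
  by_cell <- split(profiles, paste(profiles$embryo, profiles$cell, sep = "\r"))
  keys <- paste(cells$embryo, cells$cell, sep = "\r")
  strata <- split(keys, cells$embryo)
  for (b in seq_len(n_boot)) {
    pick <- unlist(lapply(strata, function(k) sample(k, length(k), replace = TRUE)),
                   use.names = FALSE)
    df <- dplyr::bind_rows(by_cell[pick])
    boots[, b] <- fit_on(df)
  }
  alpha <- (1 - conf) / 2
  band <- apply(boots, 1, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)

  structure(
    list(
      curve = tibble(percent = grid, fit = fit,
                     lower = band[1, ], upper = band[2, ]),
      fraction = fraction, n_boot = as.integer(n_boot), conf = conf,
      n_cells = nrow(cells), n_points = nrow(profiles)
    ),
    class = "profile_fit"
  )
}

#' @export
#' @method tidy profile_fit
tidy.profile_fit <- function(x, ...) x$curve

#' @export
#' @method glance profile_fit
glance.profile_fit <- function(x, ...) {
  tibble(fraction = x$fraction, n_boot = x$n_boot, conf = x$conf,
         n_cells = x$n_cells, n_points = x$n_points,
         peak_to_trough = max(x$curve$fit) - min(x$curve$fit))
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf(
    "<profile_fit> LOWESS (span %.2f) on %d points from %d cells; %d bootstrap resamples\n",
    x$fraction, x$n_points, x$n_cells, x$n_boot
  ))
  invisible(x)
}
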