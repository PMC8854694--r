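#' Configuration for the synthetic apical-intensity image generator
#'
#' Emulates the two apical F-actin organisation patterns quantified by
#' line profiling: a junctional pattern where signal concentrates at the
#' apical cell-cell junctions (intensity peaks at the ends of the apical
#' domain) and a uniform pattern where the same integrated signal is spread
#' homogeneously along the apical path — the hallmark of the mutant
#' phenotype.
#'
#' @param image_shape `c(ny, nx)` pixels.
#' @param junction_positions List of length-2 numeric points (0-based pixel
#'   coordinates) marking the junctions bounding the apical domain; the
#'   apical path runs between consecutive junctions. At least two required.
#' @param junction_amplitude Peak amplitude added at each junction in
#'   junctional mode (arbitrary intensity units).
#' @param junction_sd Gaussian spot sigma (pixels) of a junction in
#'   junctional mode.
#' @param uniform_amplitude Intensity of the apical band in uniform mode;
#'   if `NULL`, derived so that the integrated apical signal matches the
#'   junctional mode exactly.
#' @param nucleus_polygon Polygon (data.frame `x`, `y`) of the nucleus used
#'   for normalisation.
#' @param nucleus_mean Mean intensity inside the nucleus.
#' @param baseline Constant background intensity.
#' @param noise_sd Gaussian noise standard deviation.
#' @param mode `"junctional"` or `"uniform"`.
#' @param seed Integer seed.
#' @return A list of class `profile_sim_config`.
#' @export
profile_sim_config <- function(image_shape = c(64, 64),
                               junction_positions = list(c(12, 32), c(52, 32)),
                               junction_amplitude = 200,
                               junction_sd = 1.5,
                               uniform_amplitude = NULL,
                               nucleus_polygon = data.frame(
                                 x = c(24, 40, 40, 24), y = c(42, 42, 56, 56)
                               ),
                               nucleus_mean = 50,
                               baseline = 10,
                               noise_sd = 0,
                               mode = c("junctional", "uniform"),
                               seed = 1L) {
  mode <- match.arg(mode)
  check_number(junction_amplitude, "junction_amplitude", 0)
  check_number(junction_sd, "junction_sd", 1e-9)
  check_number(nucleus_mean, "nucleus_mean", 0)
  check_number(baseline, "baseline", 0)
  check_number(noise_sd, "noise_sd", 0)
  if (!is.null(uniform_amplitude)) check_number(uniform_amplitude, "uniform_amplitude", 0)
  if (length(junction_positions) < 2) {
    stop_bad_arg("need at least two junction positions")
  }
  structure(
    list(
      image_shape = as.integer(image_shape),
      junction_positions = junction_positions,
      junction_amplitude = junction_amplitude,
      junction_sd = junction_sd,
      uniform_amplitude = uniform_amplitude,
      nucleus_polygon = nucleus_polygon,
      nucleus_mean = nucleus_mean,
      baseline = baseline,
      noise_sd = noise_sd,
      mode = mode,
      seed = as.integer(seed)
    ),
    class = "profile_sim_config"
  )
}

#' Generate a synthetic apical-intensity image with known expected profile
#'
#' In junctional mode, Gaussian spots of amplitude `junction_amplitude` are
#' placed at the junction positions; in uniform mode the same integrated
#' signal (unless `uniform_amplitude` is given) is spread evenly along a
#' band following the apical path between the outermost junctions. The
#' nucleus polygon is filled so that its pixel mean equals `nucleus_mean`,
#' providing the normaliser for [normalize_profile()].
#'
#' @param config A [profile_sim_config()].
#' @return A list with `image` (matrix), `path` (data.frame `x`, `y`: the
#'   apical path through the junctions), `nucleus` (polygon) and `truth`
#'   (list with the noise-free expected profile function evaluated on a
#'   percent grid).
#' @export
generate_profile_image <- function(config) {
  stopifnot(inherits(config, "profile_sim_config"))
  set.seed(config$seed)
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  xs <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny) - 1, nx), ny, nx)
  img <- matrix(config$baseline, ny, nx)

  jp <- do.call(rbind, config$junction_positions)
  path <- data.frame(x = jp[, 1], y = jp[, 2])
  seg_len <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  total_len <- sum(seg_len)

  # Integrated (2D) signal of the junctional pattern: each Gaussian spot
  # integrates to amplitude * 2*pi*sd^2.
  n_j <- nrow(jp)
  junctional_integral <- n_j * config$junction_amplitude * 2 * pi * config$junction_sd^2

  if (config$mode == "junctional") {
    for (k in seq_len(n_j)) {
      d2 <- (xs - jp[k, 1])^2 + (ys - jp[k, 2])^2
      img <- img + config$junction_amplitude * exp(-d2 / (2 * config$junction_sd^2))
    }
  }
  level <- NA_real_
  if (config$mode == "uniform") {
    # Uniform band of half-width w along the apical path carrying the same
    # integrated (pixel-summed) signal as the junctional pattern.
    w <- 2
    dense <- resample_polyline(path, step = 0.25)
    dmin <- matrix(Inf, ny, nx)
    for (k in seq_len(nrow(dense))) {
      d <- sqrt((xs - dense$x[k])^2 + (ys - dense$y[k])^2)
      dmin <- pmin(dmin, d)
    }
    band <- dmin <= w
    level <- config$uniform_amplitude %||% (junctional_integral / sum(band))
    img <- img + level * band
  }

  nuc_mask <- polygon_mask(config$nucleus_polygon, ny, nx)
  img[nuc_mask] <- config$nucleus_mean

  if (config$noise_sd > 0) {
    img <- img + matrix(rnorm(ny * nx, 0, config$noise_sd), ny, nx)
  }

  # Noise-free expected profile along the path at percent positions.
  pct <- seq(0, 100, by = 1)
  s_at <- pct / 100 * total_len
  pts <- resample_polyline(path, step = total_len / 400)
  exp_at <- function(s) {
    p <- c(approx(pts$s, pts$x, xout = s, ties = "ordered")$y,
           approx(pts$s, pts$y, xout = s, ties = "ordered")$y)
    if (config$mode == "junctional") {
      config$baseline + sum(config$junction_amplitude *
        exp(-((p[1] - jp[, 1])^2 + (p[2] - jp[, 2])^2) /
              (2 * config$junction_sd^2)))
    } else {
      config$baseline + level
    }
  }
  truth <- tibble(
    percent = pct,
    expected_intensity = vapply(s_at, exp_at, numeric(1)),
    expected_normalized = vapply(s_at, exp_at, numeric(1)) / config$nucleus_mean
  )

  list(image = img, path = path, nucleus = config$nucleus_polygon, truth = truth)
}
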