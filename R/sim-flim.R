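#' Configuration for the synthetic FLIM stack generator
#'
#' Describes a field of view containing polygonal regions of known
#' fluorescence lifetime. Each pixel inside a region receives a Poisson
#' photon-decay histogram sampled from a mono-exponential decay, periodic
#' with the excitation repetition rate; pixels outside every region carry
#' only a uniform background count level.
#'
#' @param image_shape Integer length-2, `c(ny, nx)` pixels.
#' @param regions List of regions, each a list with `polygon` (data.frame
#'   `x`, `y` in 0-based pixel coordinates) and `tau_ns` (true lifetime, ns).
#' @param rep_rate Laser repetition rate in Hz (acquisition used 20 MHz).
#' @param n_time_bins Bins per excitation period. The default of 512 keeps
#'   the bin-discretization bias of the phase-lifetime estimator below 0.5%
#'   across the tension-sensitive range (the bias scales with the inverse
#'   square of the bin count and is worst for short lifetimes).
#' @param photons_per_pixel_mean Expected photons per region pixel.
#' @param background_count_level Expected total background counts per pixel
#'   outside the regions (spread uniformly over the time bins).
#' @param pixel_size_nm Pixel pitch in nm (acquisition used 135 nm/px).
#' @param seed Integer seed.
#' @return A list of class `flim_sim_config`.
#' @export
flim_sim_config <- function(image_shape = c(32, 32),
                            regions = list(),
                            rep_rate = 20e6,
                            n_time_bins = 512,
                            photons_per_pixel_mean = 1e4,
                            background_count_level = 5,
                            pixel_size_nm = 135,
                            seed = 1L) {
  check_number(rep_rate, "rep_rate", 1e-9)
  check_number(n_time_bins, "n_time_bins", 8)
  check_number(photons_per_pixel_mean, "photons_per_pixel_mean", 0)
  check_number(background_count_level, "background_count_level", 0)
  check_number(pixel_size_nm, "pixel_size_nm", 1e-9)
  if (length(image_shape) != 2 || any(image_shape < 1)) {
    stop_bad_arg("`image_shape` must be c(ny, nx) with positive entries")
  }
  for (r in regions) {
    if (is.null(r$polygon) || is.null(r$tau_ns)) {
      stop_bad_arg("each region needs `polygon` and `tau_ns`")
    }
    check_number(r$tau_ns, "tau_ns", 1e-12)
    if (any(r$polygon$x < 0 | r$polygon$x > image_shape[2] - 1 |
            r$polygon$y < 0 | r$polygon$y > image_shape[1] - 1)) {
      stop_bad_arg("region polygon lies outside the image")
    }
  }
  structure(
    list(
      image_shape = as.integer(image_shape), regions = regions,
      rep_rate = rep_rate, n_time_bins = as.integer(n_time_bins),
      photons_per_pixel_mean = photons_per_pixel_mean,
      background_count_level = background_count_level,
      pixel_size_nm = pixel_size_nm, seed = as.integer(seed)
    ),
    class = "flim_sim_config"
  )
}

# Expected fraction of photons per time bin for a mono-exponential lifetime
# tau (seconds) under periodic excitation with period Tp: the steady-state
# (wrapped) decay integrated over each bin, normalized to sum 1. The wrap
# factor is constant across bins and cancels in the normalization.
decay_bin_fractions <- function(tau_s, rep_rate, n_bins) {
  Tp <- 1 / rep_rate
  edges <- seq(0, Tp, length.out = n_bins + 1)
  ci <- exp(-edges[-(n_bins + 1)] / tau_s) - exp(-edges[-1] / tau_s)
  ci / sum(ci)
}

#' Generate a synthetic FLIM photon-decay stack with known region lifetimes
#'
#' Every pixel inside a configured region gets a decay histogram drawn
#' `counts[k] ~ Poisson(photons * p[k])` where `p` is the bin-integrated
#' wrapped mono-exponential for that region's lifetime. Background pixels
#' receive uniform Poisson counts totalling `background_count_level` on
#' average, so a count threshold between the background level and the
#' region level separates them exactly in expectation.
#'
#' Lifetimes at or beyond `1 / (2 * pi * rep_rate)` times the period are
#' close to the phasor aliasing regime; such configurations are generated
#' but flagged with a warning.
#'
#' @param config A [flim_sim_config()].
#' @return A list with `stack` (a [flim_stack()]), `truth` (tibble of region
#'   lifetimes) and `region_map` (integer matrix, 0 = background).
#' @export
generate_flim_stack <- function(config) {
  stopifnot(inherits(config, "flim_sim_config"))
  set.seed(config$seed)
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  nb <- config$n_time_bins
  Tp <- 1 / config$rep_rate
  decay <- array(0, dim = c(ny, nx, nb))
  region_map <- matrix(0L, ny, nx)

  for (i in seq_along(config$regions)) {
    r <- config$regions[[i]]
    tau_s <- r$tau_ns * 1e-9
    if (tau_s >= Tp / (2 * pi)) {
      warn(sprintf(
        "region %d lifetime %.3g ns is at or beyond the aliasing limit %.3g ns for a %.3g MHz repetition rate",
        i, r$tau_ns, Tp / (2 * pi) * 1e9, config$rep_rate / 1e6
      ))
    }
    mask <- polygon_mask(r$polygon, ny, nx)
    region_map[mask] <- i
    frac <- decay_bin_fractions(tau_s, config$rep_rate, nb)
    idx <- which(mask)
    n_px <- length(idx)
    if (n_px == 0) next
    lam <- outer(rep(config$photons_per_pixel_mean, n_px), frac)
    counts <- matrix(rpois(n_px * nb, lam), n_px, nb)
    for (k in seq_len(nb)) {
      plane <- decay[, , k]
      plane[idx] <- counts[, k]
      decay[, , k] <- plane
    }
  }

  bg_idx <- which(region_map == 0L)
  if (length(bg_idx) > 0 && config$background_count_level > 0) {
    lam_bg <- config$background_count_level / nb
    for (k in seq_len(nb)) {
      plane <- decay[, , k]
      plane[bg_idx] <- rpois(length(bg_idx), lam_bg)
      decay[, , k] <- plane
    }
  }

  truth <- tibble(
    region = seq_along(config$regions),
    tau_ns = vapply(config$regions, function(r) r$tau_ns, numeric(1)),
    n_pixels = vapply(seq_along(config$regions),
                      function(i) sum(region_map == i), integer(1))
  )
  list(
    stack = flim_stack(decay, rep_rate = config$rep_rate,
                       pixel_size_nm = config$pixel_size_nm),
    truth = truth,
    region_map = region_map
  )
}
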