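# Shared fixture builders. Everything is generated in code; no binary files.

# A minimal hand-built track table: one division, mother at (0, -35) moving
# to the apical surface, two daughters with known displacements. Centre at
# the origin unless shifted.
tiny_track_table <- function(centre = c(0, 0),
                             d1_final = c(3, -39),   # outward: basal-ish
                             d2_final = c(0, -30)) { # inward: apical
  mother <- tibble::tibble(
    embryo_id = "e1", division_id = "e1_div_01",
    track_id = "e1_div_01_mother", role = "mother",
    frame = 1:3,
    x_um = c(0, 0, 0), y_um = c(-45, -40, -35)
  )
  d1 <- tibble::tibble(
    embryo_id = "e1", division_id = "e1_div_01",
    track_id = "e1_div_01_daughter_1", role = "daughter_1",
    frame = 4:6,
    x_um = seq(1, d1_final[1], length.out = 3),
    y_um = seq(-36, d1_final[2], length.out = 3)
  )
  d2 <- tibble::tibble(
    embryo_id = "e1", division_id = "e1_div_01",
    track_id = "e1_div_01_daughter_2", role = "daughter_2",
    frame = 4:6,
    x_um = seq(-1, d2_final[1], length.out = 3),
    y_um = seq(-34, d2_final[2], length.out = 3)
  )
  tb <- dplyr::bind_rows(mother, d1, d2)
  tb$t_min <- tb$frame * 7.5
  tb$centre_x_um <- centre[1]
  tb$centre_y_um <- centre[2]
  tb
}

# Noiseless decay stack: per-pixel histograms equal to the *expected*
# bin-integrated wrapped mono-exponential counts (no Poisson sampling),
# for closed-form phasor checks.
noiseless_stack <- function(tau_ns, ny = 4, nx = 4, photons = 1e6,
                            rep_rate = 20e6, n_bins = 512) {
  frac <- epiquant:::decay_bin_fractions(tau_ns * 1e-9, rep_rate, n_bins)
  decay <- array(rep(photons * frac, each = ny * nx), dim = c(ny, nx, n_bins))
  flim_stack(decay, rep_rate = rep_rate)
}

# Rotate + translate a track table (points and centres jointly).
rigid_transform_tracks <- function(tracks, angle_rad, shift = c(0, 0)) {
  R <- matrix(c(cos(angle_rad), sin(angle_rad),
                -sin(angle_rad), cos(angle_rad)), 2, 2)
  xy <- as.matrix(tracks[, c("x_um", "y_um")]) %*% t(R)
  ce <- as.matrix(tracks[, c("centre_x_um", "centre_y_um")]) %*% t(R)
  tracks$x_um <- xy[, 1] + shift[1]
  tracks$y_um <- xy[, 2] + shift[2]
  tracks$centre_x_um <- ce[, 1] + shift[1]
  tracks$centre_y_um <- ce[, 2] + shift[2]
  tracks
}

# Independent two-sided Fisher oracle: enumerate every table with the
# observed margins and sum the probabilities (computed from binomial
# coefficients, not dhyper) of tables no more probable than the observed.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  supp <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, supp) + lchoose(r2, c1 - supp) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[supp == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
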