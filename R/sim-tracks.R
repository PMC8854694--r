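#' Configuration for the synthetic embryo track generator
#'
#' Describes an idealised 2D (midsagittal-plane) egg-cylinder embryo in which
#' mother cells divide at the apical surface of the epiblast and each daughter
#' subsequently moves either apically (towards the embryonic-region centre)
#' or basally (towards the basement membrane). Daughter fates are sampled,
#' not emergent: the configured probabilities are the ground truth the
#' tracking pipeline is expected to recover.
#'
#' The default direction probabilities reproduce the observed study
#' conditions: in wild-type epiblast 51/56 daughters move basally; in the
#' mutant half the daughters (33/66) move apically, and 29/33 of apical
#' movers are the more apically positioned sibling.
#'
#' @param n_embryos Number of embryos.
#' @param n_divisions_per_embryo Division events simulated per embryo: a
#'   single count, or a length-`n_embryos` vector for uneven designs (the
#'   study design has 28 wild-type divisions over 3 embryos).
#' @param frame_interval Minutes between frames (live imaging used 7.5 min).
#' @param n_frames Total frames per embryo (>= 2).
#' @param centre Length-2 numeric, embryonic-region centre (micrometres) before
#'   jitter; the generated table carries it per frame.
#' @param epiblast_radius Radius (um) of the apical surface where mothers
#'   divide; must be positive and smaller than `basement_radius`.
#' @param basement_radius Radius (um) of the basement membrane circle.
#' @param p_basal_wt Probability a wild-type daughter's net movement is basal.
#' @param p_apical_mut Marginal probability a mutant daughter's net movement
#'   is apical. Fates are drawn per division (delamination hits one daughter
#'   at a time), so at the default of 0.5 every mutant division has exactly
#'   one apical mover.
#' @param sibling_apical_share Given that exactly one daughter of a division
#'   moves apically, the probability that it is the apical sibling.
#' @param genotype `"wildtype"` or `"mutant"`; selects which probability
#'   applies.
#' @param jitter_sd Standard deviation (um) of the rigid per-frame stage
#'   jitter added identically to every coordinate and to the centre. Jitter
#'   is applied after ground-truth labelling and is quantized to a dyadic
#'   grid so that jitter correction cancels it exactly.
#' @param n_follow_frames Frames a daughter is followed after division. The
#'   default (11 frames, 82.5 min at 7.5 min/frame) matches the longest
#'   follow-up shown in the live-imaging experiment.
#' @param n_mother_frames Frames of mother track before division.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return A list of class `embryo_sim_config`.
#' @export
embryo_sim_config <- function(n_embryos = 3,
                              n_divisions_per_embryo = 10,
                              frame_interval = 7.5,
                              n_frames = 30,
                              centre = c(0, 0),
                              epiblast_radius = 35,
                              basement_radius = 60,
                              p_basal_wt = 51 / 56,
                              p_apical_mut = 0.5,
                              sibling_apical_share = 29 / 33,
                              genotype = c("wildtype", "mutant"),
                              jitter_sd = 0,
                              n_follow_frames = 11,
                              n_mother_frames = 3,
                              seed = 1L) {
  genotype <- match.arg(genotype)
  check_number(n_embryos, "n_embryos", 1)
  if (!length(n_divisions_per_embryo) %in% c(1L, as.integer(n_embryos))) {
    stop_bad_arg("`n_divisions_per_embryo` must have length 1 or n_embryos")
  }
  for (v in n_divisions_per_embryo) check_number(v, "n_divisions_per_embryo", 1)
  if (length(n_divisions_per_embryo) == 1L) {
    n_divisions_per_embryo <- rep(n_divisions_per_embryo, n_embryos)
  }
  check_number(frame_interval, "frame_interval", 1e-9)
  check_number(n_frames, "n_frames", 2)
  check_prob(p_basal_wt, "p_basal_wt")
  check_prob(p_apical_mut, "p_apical_mut")
  check_prob(sibling_apical_share, "sibling_apical_share")
  check_number(epiblast_radius, "epiblast_radius", 1e-9)
  check_number(basement_radius, "basement_radius", epiblast_radius + 1e-9)
  check_number(jitter_sd, "jitter_sd", 0)
  check_number(n_follow_frames, "n_follow_frames", 1)
  check_number(n_mother_frames, "n_mother_frames", 1)
  if (!all(is.finite(centre)) || length(centre) != 2) {
    stop_bad_arg("`centre` must be two finite numbers")
  }
  needed <- n_mother_frames + n_follow_frames + 2
  if (n_frames < needed) {
    stop_bad_arg(sprintf(
      "n_frames = %d too small: need at least %d for %d mother frames and %d follow-up frames",
      n_frames, needed, n_mother_frames, n_follow_frames
    ))
  }
  structure(
    list(
      n_embryos = as.integer(n_embryos),
      n_divisions_per_embryo = as.integer(n_divisions_per_embryo),
      frame_interval = frame_interval,
      n_frames = as.integer(n_frames),
      centre = as.numeric(centre),
      epiblast_radius = epiblast_radius,
      basement_radius = basement_radius,
      p_basal_wt = p_basal_wt,
      p_apical_mut = p_apical_mut,
      sibling_apical_share = sibling_apical_share,
      genotype = genotype,
      jitter_sd = jitter_sd,
      n_follow_frames = as.integer(n_follow_frames),
      n_mother_frames = as.integer(n_mother_frames),
      seed = as.integer(seed)
    ),
    class = "embryo_sim_config"
  )
}

#' Generate synthetic division tracks with known daughter fates
#'
#' Produces a track table in the canonical schema (one mother and two
#' daughter tracks per division, per-frame embryonic-region centre columns)
#' together with the ground-truth direction label and sibling identity of
#' every daughter. Mothers approach the apical surface before dividing
#' (interkinetic nuclear migration brings mitoses to the apical side);
#' daughters then travel a net distance whose direction angle relative to
#' the mother-to-centre reference vector is drawn strictly inside (0, 90)
#' degrees for apical fates and (90, 180) for basal fates, so noise-free
#' classification is exact.
#'
#' Rigid per-frame jitter (if configured) is added identically to positions
#' and centre columns after ground truth is recorded; both are quantized to
#' a dyadic coordinate grid so that [correct_jitter()] removes the jitter
#' bit-exactly.
#'
#' @param config An [embryo_sim_config()].
#' @return A list with elements `tracks` (tibble: `embryo_id`, `division_id`,
#'   `track_id`, `role`, `frame`, `t_min`, `x_um`, `y_um`, `centre_x_um`,
#'   `centre_y_um`) and `truth` (tibble per daughter: true direction,
#'   sibling identity, true d and theta).
#' @export
#' @examples
#' sim <- generate_embryo_tracks(embryo_sim_config(n_embryos = 1, seed = 7))
#' head(sim$tracks)
generate_embryo_tracks <- function(config) {
  stopifnot(inherits(config, "embryo_sim_config"))
  set.seed(config$seed)
  cfg <- config
  p_apical <- switch(cfg$genotype,
    wildtype = 1 - cfg$p_basal_wt,
    mutant = cfg$p_apical_mut
  )

  rows <- list()
  truth <- list()
  for (e in seq_len(cfg$n_embryos)) {
    embryo_id <- sprintf("embryo_%02d", e)
    for (d in seq_len(cfg$n_divisions_per_embryo[e])) {
      division_id <- sprintf("%s_div_%02d", embryo_id, d)
      # Division frame: daughters first tracked at `fd`; mother occupies
      # fd - n_mother_frames .. fd - 1.
      fd <- sample(seq(cfg$n_mother_frames + 1,
                       cfg$n_frames - cfg$n_follow_frames), 1)
      phi <- runif(1, 0, 2 * pi)
      u_out <- c(cos(phi), sin(phi))        # radially outward (basal)
      u_tan <- c(-sin(phi), cos(phi))
      centre <- cfg$centre
      mother_final <- centre + cfg$epiblast_radius * u_out

      # Mother approaches the apical surface from a more basal position.
      r_start <- cfg$epiblast_radius +
        runif(1, 0.3, 0.8) * (cfg$basement_radius - cfg$epiblast_radius)
      m_frames <- seq(fd - cfg$n_mother_frames, fd - 1)
      m_r <- seq(r_start, cfg$epiblast_radius, length.out = length(m_frames))
      m_xy <- t(vapply(m_r, function(r) centre + r * u_out, numeric(2)))
      rows[[length(rows) + 1]] <- tibble(
        embryo_id = embryo_id, division_id = division_id,
        track_id = paste0(division_id, "_mother"), role = "mother",
        frame = m_frames, x_um = m_xy[, 1], y_um = m_xy[, 2]
      )

      # Ground-truth direction labels. Fates are drawn per division, not
      # independently per daughter: delamination affects one daughter of a
      # division at a time (the observed pattern — 33 apical movers in 33
      # mutant divisions), so the division carries exactly one apical mover
      # with probability 2*min(p, 1-p), two with probability max(0, 2p-1),
      # none otherwise. The per-daughter marginal apical probability is
      # exactly `p_apical` in all cases.
      c_both <- max(0, 2 * p_apical - 1)
      b_one <- 2 * min(p_apical, 1 - p_apical)
      u <- runif(1)
      if (u < c_both) {
        dir1 <- dir2 <- "apical"
      } else if (u < c_both + b_one) {
        which_apical <- sample(1:2, 1)
        dir1 <- if (which_apical == 1) "apical" else "basal"
        dir2 <- if (which_apical == 2) "apical" else "basal"
      } else {
        dir1 <- dir2 <- "basal"
      }
      if (xor(dir1 == "apical", dir2 == "apical")) {
        apical_mover_is_apical_sib <- runif(1) < cfg$sibling_apical_share
        if (dir1 == "apical") {
          sib1 <- if (apical_mover_is_apical_sib) "apical_daughter" else "basal_daughter"
        } else {
          sib1 <- if (apical_mover_is_apical_sib) "basal_daughter" else "apical_daughter"
        }
      } else {
        sib1 <- sample(c("apical_daughter", "basal_daughter"), 1)
      }
      sib2 <- setdiff(c("apical_daughter", "basal_daughter"), sib1)
      dirs <- c(dir1, dir2)
      sibs <- c(sib1, sib2)

      # Immediately-after-division placement: siblings straddle the mother
      # position along a random axis; the apical sibling is placed strictly
      # nearer the centre.
      axis_ang <- runif(1, 0, pi)
      axis <- c(cos(axis_ang), sin(axis_ang))
      if (sum(axis * u_out) > 0) axis_in <- -axis else axis_in <- axis
      sep <- runif(1, 1.0, 2.5)             # um, half-separation
      pos_apical <- mother_final + sep * axis_in
      pos_basal <- mother_final - sep * axis_in

      d_frames <- seq(fd, fd + cfg$n_follow_frames)
      for (k in 1:2) {
        start <- if (sibs[k] == "apical_daughter") pos_apical else pos_basal
        # Net movement from the mother's final position: theta relative to
        # the mother-to-centre reference, strictly inside the half-open
        # classification ranges.
        theta_true <- if (dirs[k] == "apical") runif(1, 5, 85) else runif(1, 95, 175)
        side <- sample(c(-1, 1), 1)
        u_in <- -u_out                       # towards the centre (apical)
        ang <- theta_true * pi / 180
        move_dir <- cos(ang) * u_in + side * sin(ang) * u_tan
        d_true <- runif(1, 5, 15)
        final <- mother_final + d_true * move_dir
        path_x <- seq(start[1], final[1], length.out = length(d_frames))
        path_y <- seq(start[2], final[2], length.out = length(d_frames))
        role <- paste0("daughter_", k)
        rows[[length(rows) + 1]] <- tibble(
          embryo_id = embryo_id, division_id = division_id,
          track_id = paste0(division_id, "_", role), role = role,
          frame = d_frames, x_um = path_x, y_um = path_y
        )
        truth[[length(truth) + 1]] <- tibble(
          embryo_id = embryo_id, division_id = division_id,
          track_id = paste0(division_id, "_", role), role = role,
          genotype = cfg$genotype,
          true_direction = dirs[k], true_sibling = sibs[k],
          true_d_um = d_true, true_theta_deg = theta_true
        )
      }
    }
  }

  tracks <- dplyr::bind_rows(rows)
  tracks$t_min <- tracks$frame * cfg$frame_interval
  tracks$centre_x_um <- cfg$centre[1]
  tracks$centre_y_um <- cfg$centre[2]

  # Quantize, then add rigid per-frame jitter (quantized to the same grid)
  # identically to coordinates and centre. Ground truth is already recorded.
  tracks$x_um <- quantize_coord(tracks$x_um)
  tracks$y_um <- quantize_coord(tracks$y_um)
  tracks$centre_x_um <- quantize_coord(tracks$centre_x_um)
  tracks$centre_y_um <- quantize_coord(tracks$centre_y_um)
  if (cfg$jitter_sd > 0) {
    key <- paste(tracks$embryo_id, tracks$frame)
    ukey <- unique(key)
    jx <- quantize_coord(rnorm(length(ukey), 0, cfg$jitter_sd))
    jy <- quantize_coord(rnorm(length(ukey), 0, cfg$jitter_sd))
    idx <- match(key, ukey)
    tracks$x_um <- tracks$x_um + jx[idx]
    tracks$y_um <- tracks$y_um + jy[idx]
    tracks$centre_x_um <- tracks$centre_x_um + jx[idx]
    tracks$centre_y_um <- tracks$centre_y_um + jy[idx]
  }

  tracks <- dplyr::arrange(tracks, .data$embryo_id, .data$track_id, .data$frame)
  tracks <- tracks[, c("embryo_id", "division_id", "track_id", "role", "frame",
                       "t_min", "x_um", "y_um", "centre_x_um", "centre_y_um")]
  list(tracks = tracks, truth = dplyr::bind_rows(truth))
}
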