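#' Correct stage jitter by re-expressing coordinates relative to the centre
#'
#' Live imaging of cultured embryos drifts; the correction subtracts the
#' per-frame embryonic-region centre from every coordinate, so that all
#' downstream geometry is computed in the centre's reference frame. After
#' correction the centre columns are identically zero, which makes the
#' operation idempotent.
#'
#' @param tracks A track table (tibble) with columns `x_um`, `y_um`,
#'   `centre_x_um`, `centre_y_um` and `frame`.
#' @return The corrected track table.
#' @export
#' @examples
#' sim <- generate_embryo_tracks(embryo_sim_config(n_embryos = 1, seed = 2))
#' corrected <- correct_jitter(sim$tracks)
#' all(corrected$centre_x_um == 0)
correct_jitter <- function(tracks) {
  req <- c("x_um", "y_um", "centre_x_um", "centre_y_um", "frame")
  missing_cols <- setdiff(req, names(tracks))
  if (length(missing_cols) > 0) {
    stop_bad_arg(paste0("track table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  bad <- !is.finite(tracks$centre_x_um) | !is.finite(tracks$centre_y_um)
  if (any(bad)) {
    stop_bad_arg(sprintf(
      "embryonic-region centre missing for frame(s): %s",
      paste(sort(unique(tracks$frame[bad])), collapse = ", ")
    ))
  }
  tracks$x_um <- tracks$x_um - tracks$centre_x_um
  tracks$y_um <- tracks$y_um - tracks$centre_y_um
  tracks$centre_x_um <- 0
  tracks$centre_y_um <- 0
  tracks
}

#' Classify a daughter's movement direction from its travel angle
#'
#' Movement with an angle below 90 degrees (towards the embryonic-region
#' centre) is apical; above 90 degrees, basal. Exactly 90 degrees is a
#' measure-zero boundary case assigned to basal and flagged.
#'
#' @param theta Numeric vector of direction angles in degrees, in
#'   \[0, 180\].
#' @return A tibble with columns `theta_deg`, `direction`
#'   (`"apical"`/`"basal"`) and `boundary_tie` (logical).
#' @export
#' @examples
#' classify_direction(c(45, 135))
classify_direction <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 180)) {
    stop_bad_arg("`theta` must be finite and within [0, 180] degrees")
  }
  tibble(
    theta_deg = theta,
    direction = ifelse(theta < 90, "apical", "basal"),
    boundary_tie = theta == 90
  )
}

# Internal: rows of one track at one frame, or NULL.
track_at <- function(tracks, id, frame) {
  r <- tracks[tracks$track_id == id & tracks$frame == frame, , drop = FALSE]
  if (nrow(r) == 0) NULL else r
}

#' Quantify daughter-cell movement after apical divisions
#'
#' The central tracking analysis. For every division (a mother track plus
#' two daughter tracks sharing a `division_id`) it computes, after jitter
#' correction:
#'
#' * `d_um` — net distance travelled by each daughter, from the mother's
#'   position immediately prior to division to the daughter's final tracked
#'   position (or a fixed follow-up horizon);
#' * `theta_deg` — the angle between the reference vector (mother position
#'   to embryonic-region centre) and the daughter's net movement vector;
#' * `direction` — apical (theta < 90) or basal (theta > 90) call;
#' * `sibling_position` — which daughter lay nearer the centre immediately
#'   after the division (`"apical_daughter"`) and which farther
#'   (`"basal_daughter"`);
#' * per-division geometry: the division angle (angle between the
#'   daughter-to-daughter axis and the midpoint-to-centre vector, folded to
#'   \[0, 90\] degrees, with an orientation bin) and, when a basement
#'   reference is supplied, the division position (distance from the mother's
#'   final position to the base of the epiblast).
#'
#' The division frame is the first frame at which the daughters are tracked;
#' "immediately prior" is `prior_offset` frames before it (mother), and
#' "immediately after" is `after_offset` frames after it (daughters).
#' Events with missing mother or daughter observations, coincident
#' daughters, or zero-length movement vectors are excluded with a logged
#' reason rather than silently dropped.
#'
#' @param tracks Track table with columns `embryo_id`, `division_id`,
#'   `track_id`, `role` (`"mother"`, `"daughter_1"`, `"daughter_2"`),
#'   `frame`, `t_min`, `x_um`, `y_um`, `centre_x_um`, `centre_y_um`.
#' @param horizon_frames Optional fixed follow-up horizon: daughters are
#'   evaluated at most this many frames after the division frame.
#' @param prior_offset Frames before the division frame at which the mother's
#'   final position is taken (default 1).
#' @param after_offset Frames after the division frame at which
#'   "immediately after division" positions are taken (default 0, i.e. the
#'   daughters' first tracked frame).
#' @param basement_reference Optional reference for division position: a
#'   list `list(type = "circle", centre = c(x, y), radius = r)`, a
#'   `list(type = "polyline", points = data.frame(x, y))`, or a
#'   `list(type = "point", point = c(x, y))`, in micrometres in the
#'   jitter-corrected frame.
#' @param orientation_breaks Bin edges (degrees) for division-orientation
#'   labels on the folded division angle: below the first edge `"parallel"`,
#'   between `"oblique"`, above the second `"orthogonal"`.
#' @return An object of class `division_analysis`: a list with tibbles
#'   `daughters`, `divisions`, `exclusions` and the parameter echo
#'   `params`. `tidy()` returns the daughters table.
#' @export
#' @examples
#' sim <- generate_embryo_tracks(embryo_sim_config(n_embryos = 1, seed = 3))
#' res <- analyze_divisions(sim$tracks)
#' dplyr::count(tidy(res), direction)
analyze_divisions <- function(tracks,
                              horizon_frames = NULL,
                              prior_offset = 1L,
                              after_offset = 0L,
                              basement_reference = NULL,
                              orientation_breaks = c(30, 60)) {
  tracks <- correct_jitter(tracks)
  if (!"division_id" %in% names(tracks)) {
    stop_bad_arg("track table needs a `division_id` column linking mothers and daughters")
  }
  dup <- duplicated(tracks[, c("embryo_id", "track_id", "frame")])
  if (any(dup)) {
    stop_bad_arg("duplicate (track_id, frame) rows in track table")
  }

  daughters <- list()
  divisions <- list()
  exclusions <- list()
  note_exclusion <- function(division_id, track_id, reason) {
    exclusions[[length(exclusions) + 1]] <<- tibble(
      division_id = division_id, track_id = track_id %||% NA_character_,
      reason = reason
    )
  }

  for (div in unique(tracks$division_id)) {
    tt <- tracks[tracks$division_id == div, , drop = FALSE]
    embryo_id <- tt$embryo_id[1]
    mother <- tt[tt$role == "mother", , drop = FALSE]
    d1 <- tt[tt$role == "daughter_1", , drop = FALSE]
    d2 <- tt[tt$role == "daughter_2", , drop = FALSE]
    if (nrow(d1) == 0 || nrow(d2) == 0 || nrow(mother) == 0) {
      note_exclusion(div, NULL, "missing mother or daughter track")
      next
    }
    division_frame <- min(c(d1$frame, d2$frame))
    m_row <- mother[mother$frame == division_frame - prior_offset, , drop = FALSE]
    if (nrow(m_row) == 0) {
      note_exclusion(div, mother$track_id[1], sprintf(
        "mother not tracked at frame %d (division frame %d minus offset %d)",
        division_frame - prior_offset, division_frame, prior_offset
      ))
      next
    }
    mother_final <- c(m_row$x_um, m_row$y_um)
    # Reference vector: mother's final position to the embryonic-region
    # centre (origin after jitter correction).
    ref_vec <- -mother_final
    if (sqrt(sum(ref_vec^2)) == 0) {
      note_exclusion(div, m_row$track_id, "mother coincides with the embryonic-region centre")
      next
    }

    after_frame <- division_frame + after_offset
    a1 <- track_at(tt, d1$track_id[1], after_frame)
    a2 <- track_at(tt, d2$track_id[1], after_frame)
    sibling <- c(daughter_1 = NA_character_, daughter_2 = NA_character_)
    sibling_tie <- FALSE
    div_angle <- NA_real_
    orientation <- NA_character_
    if (is.null(a1) || is.null(a2)) {
      note_exclusion(div, NULL, sprintf(
        "daughter missing at first post-division frame %d; sibling positions and division angle undefined",
        after_frame
      ))
    } else {
      p1 <- c(a1$x_um, a1$y_um)
      p2 <- c(a2$x_um, a2$y_um)
      r1 <- sqrt(sum(p1^2))
      r2 <- sqrt(sum(p2^2))
      if (r1 < r2) {
        sibling <- c(daughter_1 = "apical_daughter", daughter_2 = "basal_daughter")
      } else if (r2 < r1) {
        sibling <- c(daughter_1 = "basal_daughter", daughter_2 = "apical_daughter")
      } else {
        sibling_tie <- TRUE
        first <- order(c(a1$track_id, a2$track_id))[1]
        sibling <- if (first == 1) {
          c(daughter_1 = "apical_daughter", daughter_2 = "basal_daughter")
        } else {
          c(daughter_1 = "basal_daughter", daughter_2 = "apical_daughter")
        }
      }
      if (all(p1 == p2)) {
        note_exclusion(div, NULL, "coincident daughters at first post-division frame; division angle undefined")
      } else {
        axis_vec <- p2 - p1
        midpoint <- (p1 + p2) / 2
        centre_vec <- -midpoint
        raw <- angle_between(axis_vec, centre_vec)
        if (is.na(raw)) {
          note_exclusion(div, NULL, "division midpoint coincides with the centre; division angle undefined")
        } else {
          div_angle <- min(raw, 180 - raw)
          orientation <- cut(div_angle,
            breaks = c(-Inf, orientation_breaks, Inf),
            labels = c("parallel", "oblique", "orthogonal")
          )
          orientation <- as.character(orientation)
        }
      }
    }

    division_distance <- NA_real_
    if (!is.null(basement_reference)) {
      division_distance <- division_position(mother_final, basement_reference)
    }
    divisions[[length(divisions) + 1]] <- tibble(
      embryo_id = embryo_id, division_id = div,
      division_frame = division_frame,
      mother_x_um = mother_final[1], mother_y_um = mother_final[2],
      division_angle_deg = div_angle, orientation = orientation,
      division_distance_um = division_distance,
      sibling_tie = sibling_tie
    )

    for (role in c("daughter_1", "daughter_2")) {
      dt <- tt[tt$role == role, , drop = FALSE]
      post <- dt[dt$frame >= division_frame, , drop = FALSE]
      if (!is.null(horizon_frames)) {
        post <- post[post$frame <= division_frame + horizon_frames, , drop = FALSE]
      }
      if (nrow(post) == 0) {
        note_exclusion(div, dt$track_id[1], "no post-division frames within horizon")
        next
      }
      fin <- post[which.max(post$frame), , drop = FALSE]
      final_pos <- c(fin$x_um, fin$y_um)
      move_vec <- final_pos - mother_final
      d_um <- sqrt(sum(move_vec^2))
      if (d_um == 0) {
        note_exclusion(div, dt$track_id[1], "zero net movement; direction angle undefined")
        daughters[[length(daughters) + 1]] <- tibble(
          embryo_id = embryo_id, division_id = div, track_id = dt$track_id[1],
          role = role, d_um = 0, theta_deg = NA_real_,
          direction = NA_character_, boundary_tie = FALSE,
          sibling_position = unname(sibling[role]),
          final_frame = fin$frame, excluded = TRUE
        )
        next
      }
      theta <- angle_between(ref_vec, move_vec)
      cls <- classify_direction(theta)
      daughters[[length(daughters) + 1]] <- tibble(
        embryo_id = embryo_id, division_id = div, track_id = dt$track_id[1],
        role = role, d_um = d_um, theta_deg = theta,
        direction = cls$direction, boundary_tie = cls$boundary_tie,
        sibling_position = unname(sibling[role]),
        final_frame = fin$frame, excluded = FALSE
      )
    }
  }

  structure(
    list(
      daughters = dplyr::bind_rows(daughters),
      divisions = dplyr::bind_rows(divisions),
      exclusions = if (length(exclusions) > 0) dplyr::bind_rows(exclusions) else
        tibble(division_id = character(), track_id = character(), reason = character()),
      params = list(
        horizon_frames = horizon_frames, prior_offset = prior_offset,
        after_offset = after_offset,
        orientation_breaks = orientation_breaks,
        basement_reference = basement_reference
      )
    ),
    class = "division_analysis"
  )
}

#' @export
#' @method tidy division_analysis
tidy.division_analysis <- function(x, ...) x$daughters

#' @export
#' @method glance division_analysis
glance.division_analysis <- function(x, ...) {
  cls <- x$daughters[!x$daughters$excluded, , drop = FALSE]
  tibble(
    n_divisions = nrow(x$divisions),
    n_daughters = nrow(x$daughters),
    n_classified = nrow(cls),
    n_excluded = sum(x$daughters$excluded) + nrow(x$exclusions),
    prop_basal = mean(cls$direction == "basal"),
    prop_apical = mean(cls$direction == "apical")
  )
}

#' @export
print.division_analysis <- function(x, ...) {
  g <- glance(x)
  cat("<division_analysis>\n")
  cat(sprintf("  %d divisions, %d daughters (%d classified, %d exclusion records)\n",
              g$n_divisions, g$n_daughters, g$n_classified, g$n_excluded))
  cat(sprintf("  apical %.1f%% / basal %.1f%%\n",
              100 * g$prop_apical, 100 * g$prop_basal))
  invisible(x)
}

#' Net displacement of a daughter from the mother's pre-division position
#'
#' @param mother_position Length-2 numeric (um): the mother immediately
#'   prior to division.
#' @param daughter_final Length-2 numeric (um): the daughter at its final
#'   tracked position.
#' @return A list with `d_um` (Euclidean distance) and `vector` (length-2
#'   movement vector).
#' @export
#' @examples
#' daughter_displacement(c(0, 0), c(3, 4))$d_um # 5
daughter_displacement <- function(mother_position, daughter_final) {
  v <- daughter_final - mother_position
  list(d_um = sqrt(sum(v^2)), vector = v)
}

#' Direction angle of daughter movement relative to the centre reference
#'
#' The angle, in degrees in \[0, 180\], between the reference vector (from
#' the mother's pre-division position to the embryonic-region centre) and
#' the daughter's net movement vector. 0 degrees is movement straight
#' towards the centre (apical), 180 straight away (basal).
#'
#' @param mother_position Length-2 numeric (um).
#' @param daughter_final Length-2 numeric (um).
#' @param centre Length-2 numeric (um), the embryonic-region centre.
#' @return Angle in degrees, or `NA` with a warning if either vector has
#'   zero length (unclassifiable).
#' @export
#' @examples
#' direction_angle(c(0, 0), c(5, 0), centre = c(10, 0)) # 0
#' direction_angle(c(0, 0), c(0, 5), centre = c(10, 0)) # 90
direction_angle <- function(mother_position, daughter_final, centre) {
  ref_vec <- centre - mother_position
  move_vec <- daughter_final - mother_position
  ang <- angle_between(ref_vec, move_vec)
  if (is.na(ang)) {
    warn("zero-length movement or reference vector; direction angle undefined")
  }
  ang
}

#' Assign apical/basal sibling identities immediately after a division
#'
#' The daughter nearer the embryonic-region centre at the first
#' post-division frame is the `apical_daughter`, the other the
#' `basal_daughter`. Exact ties are broken towards the lower track id and
#' flagged.
#'
#' @param p1,p2 Length-2 numerics (um): daughter positions immediately
#'   after division.
#' @param centre Length-2 numeric (um).
#' @param ids Character length-2: track ids of the two daughters.
#' @return A tibble with `track_id`, `sibling_position`, `tie`.
#' @export
assign_sibling_positions <- function(p1, p2, centre, ids = c("d1", "d2")) {
  r1 <- sqrt(sum((p1 - centre)^2))
  r2 <- sqrt(sum((p2 - centre)^2))
  tie <- r1 == r2
  if (tie) {
    apical_first <- order(ids)[1] == 1
  } else {
    apical_first <- r1 < r2
  }
  lab <- if (apical_first) c("apical_daughter", "basal_daughter") else
    c("basal_daughter", "apical_daughter")
  tibble(track_id = ids, sibling_position = lab, tie = tie)
}

#' Division angle relative to the embryonic-region centre
#'
#' The angle between the daughter-to-daughter axis immediately after
#' division and the vector from the midpoint between the daughters to the
#' embryonic-region centre, folded to \[0, 90\] degrees for orientation
#' summaries: 90 means the division axis is orthogonal to the
#' midpoint-to-centre (apical-basal) direction.
#'
#' @param p1,p2 Length-2 numerics (um): daughter positions immediately
#'   after division.
#' @param centre Length-2 numeric (um).
#' @return Folded angle in degrees in \[0, 90\]; `NA` if the daughters
#'   coincide or the midpoint equals the centre.
#' @export
#' @examples
#' division_angle(c(0, 1), c(0, -1), centre = c(10, 0)) # 90
#' division_angle(c(1, 0), c(-1, 0), centre = c(10, 0)) # 0
division_angle <- function(p1, p2, centre) {
  if (all(p1 == p2)) return(NA_real_)
  axis_vec <- p2 - p1
  centre_vec <- centre - (p1 + p2) / 2
  raw <- angle_between(axis_vec, centre_vec)
  if (is.na(raw)) return(NA_real_)
  min(raw, 180 - raw)
}

#' Distance from a division site to the base of the epiblast
#'
#' Shortest distance from the mother's position immediately prior to
#' division to a basement-membrane reference, which may be a circle model
#' (distance to the circle line), a polyline traced along the basement
#' membrane, or a single point.
#'
#' @param mother_position Length-2 numeric (um), jitter-corrected.
#' @param reference A list with `type` one of `"circle"` (`centre`,
#'   `radius`), `"polyline"` (`points`: data.frame `x`, `y`) or `"point"`
#'   (`point`).
#' @return Distance in micrometres.
#' @export
#' @examples
#' division_position(c(40, 0), list(type = "circle", centre = c(0, 0), radius = 60))
division_position <- function(mother_position, reference) {
  if (is.null(reference$type)) stop_bad_arg("basement reference needs a `type`")
  switch(reference$type,
    circle = {
      check_number(reference$radius, "radius", 0)
      abs(sqrt(sum((mother_position - reference$centre)^2)) - reference$radius)
    },
    polyline = dist_to_polyline(mother_position, reference$points),
    point = sqrt(sum((mother_position - reference$point)^2)),
    stop_bad_arg(sprintf("unknown basement reference type '%s'", reference$type))
  )
}

#' Tabulate daughter direction calls into contingency tables
#'
#' Builds the 2x2 count tables (group by direction) underlying the
#' proportion comparisons: one overall table and one per sibling position.
#' Excluded daughters are not counted; counts therefore always sum to the
#' number of classified daughters.
#'
#' @param outcomes A tibble with columns `direction`
#'   (`"apical"`/`"basal"`), optionally `sibling_position`, and the grouping
#'   column.
#' @param group Name of the grouping column (e.g. `"genotype"`).
#' @return A tibble with columns `stratum` (`"all"`, `"apical_daughter"`,
#'   `"basal_daughter"`), the group, `apical`, `basal` and `n`.
#' @export
direction_contingency <- function(outcomes, group = "genotype") {
  if (!group %in% names(outcomes)) {
    stop_bad_arg(sprintf("grouping column '%s' not found", group))
  }
  ok <- !is.na(outcomes$direction)
  outcomes <- outcomes[ok, , drop = FALSE]
  if (nrow(outcomes) == 0) stop_bad_arg("no classified daughters to tabulate")
  count_stratum <- function(df, label) {
    df %>%
      dplyr::count(.data[[group]], .data$direction) %>%
      tidyr::pivot_wider(names_from = "direction", values_from = "n",
                         values_fill = 0L) %>%
      dplyr::mutate(stratum = label, .before = 1)
  }
  out <- count_stratum(outcomes, "all")
  if ("sibling_position" %in% names(outcomes)) {
    for (sp in c("apical_daughter", "basal_daughter")) {
      sub <- outcomes[!is.na(outcomes$sibling_position) &
                        outcomes$sibling_position == sp, , drop = FALSE]
      if (nrow(sub) > 0) out <- dplyr::bind_rows(out, count_stratum(sub, sp))
    }
  }
  for (col in c("apical", "basal")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out$n <- out$apical + out$basal
  if (any(out$n == 0)) stop_bad_arg("empty group in contingency table")
  out[, c("stratum", group, "apical", "basal", "n")]
}

#' Extract a 2x2 matrix from a direction contingency tibble
#'
#' @param contingency Output of [direction_contingency()].
#' @param stratum Which stratum to extract (default `"all"`).
#' @return A 2x2 integer matrix (rows = groups, columns = apical/basal).
#' @export
contingency_matrix <- function(contingency, stratum = "all") {
  sub <- contingency[contingency$stratum == stratum, , drop = FALSE]
  if (nrow(sub) != 2) {
    stop_bad_arg(sprintf("stratum '%s' does not define a 2x2 table", stratum))
  }
  group_col <- setdiff(names(sub), c("stratum", "apical", "basal", "n"))[1]
  m <- as.matrix(sub[, c("apical", "basal")])
  rownames(m) <- sub[[group_col]]
  m
}
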