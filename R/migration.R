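#' Per-cell migration metrics: movement, velocity, directionality
#'
#' Quantifies individually tracked migrating cells:
#'
#' * movement — total path length in micrometres (sum of segment lengths);
#' * velocity — average speed, movement divided by total elapsed time
#'   (um/min);
#' * directionality — the ratio of total distance travelled to the
#'   straight-line distance between start and end positions, so a
#'   perfectly straight path scores 1 and convoluted paths score above 1.
#'   `inverse = TRUE` reports the reciprocal (straight/total, in (0, 1]),
#'   the convention used elsewhere in the cell-migration literature; the
#'   default keeps the ratio as defined in the source workflow rather than
#'   silently flipping it.
#'
#' Cells ending exactly where they started have undefined directionality;
#' they are reported with `NA` and a note rather than dropped.
#'
#' @param tracks Tibble with columns `cell_id`, `t_min`, `x_um`, `y_um`;
#'   each cell needs >= 2 samples with strictly increasing time.
#' @param inverse Report straight-line/total ratio instead (default FALSE).
#' @return A tibble: `cell_id`, `movement_um`, `velocity_um_min`,
#'   `directionality`, `n_steps`, `note`.
#' @export
#' @examples
#' tr <- tibble::tibble(cell_id = "a", t_min = c(0, 5, 10),
#'                      x_um = c(0, 3, 3), y_um = c(0, 0, 4))
#' migration_metrics(tr)
migration_metrics <- function(tracks, inverse = FALSE) {
  req <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(req %in% names(tracks))) {
    stop_bad_arg(paste("track table needs columns:", paste(req, collapse = ", ")))
  }
  out <- lapply(split(tracks, tracks$cell_id), function(tr) {
    tr <- tr[order(tr$t_min), , drop = FALSE]
    if (nrow(tr) < 2) {
      stop_bad_arg(sprintf("cell '%s' has fewer than 2 samples", tr$cell_id[1]))
    }
    if (any(diff(tr$t_min) <= 0)) {
      stop_bad_arg(sprintf("cell '%s' has non-increasing time stamps", tr$cell_id[1]))
    }
    seg <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    movement <- sum(seg)
    duration <- tr$t_min[nrow(tr)] - tr$t_min[1]
    straight <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                       (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    note <- NA_character_
    if (straight == 0) {
      directionality <- NA_real_
      note <- "start equals end: directionality undefined"
    } else {
      directionality <- if (inverse) straight / movement else movement / straight
    }
    tibble(
      cell_id = tr$cell_id[1],
      movement_um = movement,
      velocity_um_min = movement / duration,
      directionality = directionality,
      n_steps = nrow(tr) - 1L,
      note = note
    )
  })
  dplyr::bind_rows(out)
}
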