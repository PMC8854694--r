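test_that("jitter correction subtracts the per-frame centre exactly", {
  tb <- tiny_track_table(centre = c(0, 0))
  # constant zero centre: identity
  expect_identical(correct_jitter(tb)[, c("x_um", "y_um")],
                   tb[, c("x_um", "y_um")])
  # translating points and centres of one frame cancels exactly
  tb2 <- tb
  shift <- tb2$frame == 5
  tb2$x_um[shift] <- tb2$x_um[shift] + 5
  tb2$y_um[shift] <- tb2$y_um[shift] - 3
  tb2$centre_x_um[shift] <- tb2$centre_x_um[shift] + 5
  tb2$centre_y_um[shift] <- tb2$centre_y_um[shift] - 3
  expect_identical(correct_jitter(tb2), correct_jitter(tb))
})

test_that("missing centres are reported with the offending frame", {
  tb <- tiny_track_table()
  tb$centre_x_um[tb$frame == 4] <- NA
  expect_error(correct_jitter(tb), "frame\\(s\\): 4")
})

test_that("displacement and direction angle match hand geometry", {
  expect_equal(daughter_displacement(c(0, 0), c(3, 4))$d_um, 5)
  expect_equal(direction_angle(c(0, 0), c(5, 0), centre = c(10, 0)), 0)
  expect_equal(direction_angle(c(0, 0), c(0, 5), centre = c(10, 0)), 90)
  expect_equal(direction_angle(c(0, 0), c(-4, 0), centre = c(10, 0)), 180)
  expect_warning(ang <- direction_angle(c(0, 0), c(0, 0), centre = c(10, 0)),
                 "undefined")
  expect_true(is.na(ang))
})

test_that("direction classification matches the angle ranges with 90 flagged basal", {
  cls <- classify_direction(c(45, 135, 90, 0, 180))
  expect_equal(cls$direction, c("apical", "basal", "basal", "apical", "basal"))
  expect_equal(cls$boundary_tie, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_error(classify_direction(-1), "\\[0, 180\\]")
  expect_error(classify_direction(181), "\\[0, 180\\]")
  # exhaustive oracle over a fine grid
  grid <- seq(0, 180, by = 0.25)
  oracle <- ifelse(grid < 90, "apical", "basal")
  expect_identical(classify_direction(grid)$direction, oracle)
})

test_that("sibling positions follow proximity to the centre with tie flag", {
  res <- assign_sibling_positions(c(0, 10), c(0, 20), centre = c(0, 0),
                                  ids = c("a", "b"))
  expect_equal(res$sibling_position[res$track_id == "a"], "apical_daughter")
  expect_false(any(res$tie))
  tie <- assign_sibling_positions(c(0, 10), c(10, 0), centre = c(0, 0),
                                  ids = c("b", "a"))
  expect_true(all(tie$tie))
  expect_equal(tie$sibling_position[tie$track_id == "a"], "apical_daughter")
})

test_that("division angle folds to [0, 90] and is rotation invariant", {
  expect_equal(division_angle(c(0, 1), c(0, -1), centre = c(10, 0)), 90)
  expect_equal(division_angle(c(1, 0), c(-1, 0), centre = c(10, 0)), 0)
  expect_true(is.na(division_angle(c(1, 1), c(1, 1), centre = c(10, 0))))
  rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                          sin(a) * p[1] + cos(a) * p[2])
  set.seed(1)
  for (k in 1:20) {
    p1 <- runif(2, -5, 5); p2 <- runif(2, -5, 5); ce <- runif(2, 10, 20)
    a <- runif(1, 0, 2 * pi)
    expect_equal(division_angle(rot(p1, a), rot(p2, a), rot(ce, a)),
                 division_angle(p1, p2, ce), tolerance = 1e-9)
  }
})

test_that("division position handles circle, point and polyline references", {
  expect_equal(division_position(c(40, 0),
                                 list(type = "circle", centre = c(0, 0), radius = 60)), 20)
  expect_equal(division_position(c(0, 60),
                                 list(type = "circle", centre = c(0, 0), radius = 60)), 0)
  expect_equal(division_position(c(0, 3), list(type = "point", point = c(4, 0))), 5)
  # polyline vs dense point-sampling oracle
  set.seed(7)
  poly <- data.frame(x = cumsum(runif(8, 1, 4)), y = rnorm(8, 0, 3))
  p <- c(10, 5)
  dense <- epiquant:::resample_polyline(poly, step = 1e-3)
  oracle <- min(sqrt((dense$x - p[1])^2 + (dense$y - p[2])^2))
  expect_equal(division_position(p, list(type = "polyline", points = poly)),
               oracle, tolerance = 1e-6)
  expect_error(division_position(c(0, 0), list(type = "nope")), "unknown")
})

test_that("analyze_divisions reproduces per-row arithmetic on a hand-built event", {
  tb <- tiny_track_table()
  res <- analyze_divisions(tb)
  expect_equal(nrow(res$daughters), 2)
  d1 <- res$daughters[res$daughters$role == "daughter_1", ]
  # mother final (0,-35); daughter_1 final (3,-39): d = sqrt(9+16) = 5
  expect_equal(d1$d_um, 5)
  # reference vector (0,35); movement (3,-4): theta = angle between
  expect_equal(d1$theta_deg,
               acos(sum(c(0, 35) * c(3, -4)) / (35 * 5)) * 180 / pi)
  expect_equal(d1$direction, "basal")
  d2 <- res$daughters[res$daughters$role == "daughter_2", ]
  expect_equal(d2$d_um, 5)
  expect_equal(d2$direction, "apical")
  # daughter_2 starts nearer the centre
  expect_equal(d2$sibling_position, "apical_daughter")
})

test_that("theta, d and division angle are invariant under rigid motions", {
  sim <- generate_embryo_tracks(embryo_sim_config(n_embryos = 1, seed = 21))
  base <- analyze_divisions(sim$tracks)
  set.seed(33)
  for (k in 1:10) {
    tr <- rigid_transform_tracks(sim$tracks, runif(1, 0, 2 * pi),
                                 runif(2, -100, 100))
    res <- analyze_divisions(tr)
    expect_equal(res$daughters$theta_deg, base$daughters$theta_deg,
                 tolerance = 1e-9)
    expect_equal(res$daughters$d_um, base$daughters$d_um, tolerance = 1e-9)
    expect_equal(res$divisions$division_angle_deg,
                 base$divisions$division_angle_deg, tolerance = 1e-9)
    expect_identical(res$daughters$direction, base$daughters$direction)
  }
})

test_that("noise-free synthetic data is classified in full agreement with ground truth", {
  for (gt in c("wildtype", "mutant")) {
    sim <- generate_embryo_tracks(embryo_sim_config(
      n_embryos = 3, n_divisions_per_embryo = 10, genotype = gt, seed = 17
    ))
    res <- analyze_divisions(sim$tracks)
    j <- dplyr::inner_join(res$daughters, sim$truth,
                           by = c("embryo_id", "division_id", "track_id"))
    expect_equal(nrow(j), nrow(sim$truth))
    expect_identical(j$direction, j$true_direction)
    expect_identical(j$sibling_position, j$true_sibling)
    expect_equal(j$theta_deg, j$true_theta_deg, tolerance = 1e-2)
    expect_equal(j$d_um, j$true_d_um, tolerance = 1e-4)
  }
})

test_that("a fixed follow-up horizon shortens the evaluated final frame", {
  sim <- generate_embryo_tracks(embryo_sim_config(n_embryos = 1, seed = 5))
  full <- analyze_divisions(sim$tracks)
  short <- analyze_divisions(sim$tracks, horizon_frames = 3)
  expect_true(all(short$daughters$final_frame <=
                    full$daughters$final_frame))
})

test_that("apical + basal counts equal classified daughters in contingency tables", {
  sims <- lapply(c(wildtype = "wildtype", mutant = "mutant"), function(gt) {
    sim <- generate_embryo_tracks(embryo_sim_config(
      n_embryos = 2, n_divisions_per_embryo = 8, genotype = gt, seed = 13
    ))
    out <- tidy(analyze_divisions(sim$tracks))
    out$genotype <- gt
    out
  })
  outcomes <- dplyr::bind_rows(sims)
  ct <- direction_contingency(outcomes, group = "genotype")
  all_row <- ct[ct$stratum == "all", ]
  expect_equal(sum(all_row$n), sum(!is.na(outcomes$direction)))
  m <- contingency_matrix(ct, "all")
  expect_equal(dim(m), c(2, 2))
  expect_equal(sum(m), sum(all_row$n))
})

test_that("daughters with missing tracks are excluded with logged reasons", {
  tb <- tiny_track_table()
  tb <- tb[!(tb$role == "daughter_2" & tb$frame == 4), ]
  # daughter_2 now starts at frame 5: division frame still 4 (daughter_1),
  # so daughter_2 is missing at the first post-division frame.
  res <- analyze_divisions(tb)
  expect_gt(nrow(res$exclusions), 0)
  expect_match(paste(res$exclusions$reason, collapse = " "),
               "post-division frame")
})
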