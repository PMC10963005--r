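test_that("headings are estimated from displacements with carry-forward", {
  # straight rightward walk: all headings 0
  ind <- make_walk(c(0, 1, 2, 3), rep(0, 4))
  expect_equal(estimate_heading(ind)$frames$heading_rad, rep(0, 4))

  # stationary frame inside a walk carries the previous heading
  ind2 <- make_walk(c(0, 1, 1, 2), c(0, 0, 0, 0))
  expect_equal(estimate_heading(ind2)$frames$heading_rad, rep(0, 4))

  # a fine circular path matches the tangent within the discretisation bound
  n <- 500
  t <- seq(0, 2 * pi, length.out = n)
  ind3 <- make_walk(cos(t), sin(t))
  est <- estimate_heading(ind3)$frames$heading_rad
  tangent <- (t + pi / 2) %% (2 * pi)
  d <- abs(est - tangent)
  d <- pmin(d, 2 * pi - d)
  expect_true(all(d[-n] <= 2 * pi / n + 1e-9))

  # all-stationary trajectory is unresolvable
  expect_error(estimate_heading(make_walk(rep(1, 5), rep(2, 5))),
               "heading unresolvable")
})

test_that("speed is forward displacement in body lengths per second", {
  still <- make_walk(rep(0, 5), rep(0, 5), bl = 5)
  expect_equal(speed_bl_s(still, 1)$speed_bl_s, rep(0, 4))

  # 5 mm per frame at 1 FPS with a 5 mm body = 1 BL/s
  ind <- make_walk(seq(0, 20, by = 5), rep(0, 5), bl = 5)
  sp <- speed_bl_s(ind, 1)
  expect_equal(sp$speed_bl_s, rep(1, 4))
  expect_equal(nrow(sp), 4)  # last frame dropped

  expect_error(speed_bl_s(ind, 1, body_length_mm = 0), "positive")
})

test_that("relative direction spans [0, pi] with the declared anchors", {
  expect_equal(relative_direction(0, 0, 0, 1, 0), 0)          # ahead
  expect_equal(relative_direction(0, 0, 0, -1, 0), pi)        # behind
  expect_equal(relative_direction(0, 0, 0, 0, 1), pi / 2)     # left
  expect_equal(relative_direction(0, 0, 0, 0, -1), pi / 2)    # right
  expect_true(is.na(relative_direction(1, 2, 0.3, 1, 2)))     # coincident

  # invariance under global rotation + translation (500 random instances)
  set.seed(42)
  for (i in 1:500) {
    f <- runif(2, -10, 10); p <- runif(2, -10, 10); h <- runif(1, 0, 2 * pi)
    a <- runif(1, 0, 2 * pi); shift <- runif(2, -50, 50)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    f2 <- as.vector(R %*% f) + shift
    p2 <- as.vector(R %*% p) + shift
    expect_equal(relative_direction(f2[1], f2[2], (h + a) %% (2 * pi),
                                    p2[1], p2[2]),
                 relative_direction(f[1], f[2], h, p[1], p[2]),
                 tolerance = 1e-9)
  }
})

test_that("pair metrics implement the body-length threshold and angle ranges", {
  # fossil-sized pair: interaction threshold is the summed body lengths, 12 mm
  just_in <- make_event(0, 0, 11.999, 0, bl_f = 6.5, bl_m = 5.5,
                        f_heading = 0, m_heading = 0)
  just_out <- make_event(0, 0, 12.0, 0, bl_f = 6.5, bl_m = 5.5,
                         f_heading = 0, m_heading = 0)
  expect_true(pair_metrics(just_in)$interacting)
  expect_false(pair_metrics(just_out)$interacting)   # strict inequality
  expect_equal(pair_metrics(just_out)$distance_bl, 12 / 6)

  # coincident centroids: zero distance, interacting, undefined bearings
  co <- make_event(1, 2, 1, 2, f_heading = 0, m_heading = pi / 2)
  mco <- pair_metrics(co)
  expect_equal(mco$distance_bl, 0)
  expect_true(mco$interacting)
  expect_true(is.na(mco$rel_dir_f))

  # parallel headings differ by 0, antiparallel by pi
  par <- make_event(0, 0, 5, 0, f_heading = 1, m_heading = 1)
  expect_equal(pair_metrics(par)$heading_diff, 0)
  anti <- make_event(0, 0, 5, 0, f_heading = 1,
                     m_heading = (1 + pi) %% (2 * pi))
  expect_equal(pair_metrics(anti)$heading_diff, pi, tolerance = 1e-12)

  # angle ranges over random inputs
  set.seed(7)
  ev <- make_event(runif(200, 0, 50), runif(200, 0, 50),
                   runif(200, 0, 50), runif(200, 0, 50),
                   f_heading = NA, m_heading = NA)
  m <- pair_metrics(ev)
  for (col in c("rel_dir_f", "rel_dir_m", "heading_diff")) {
    v <- m[[col]][!is.na(m[[col]])]
    expect_true(all(v >= 0 & v <= pi))
  }
  expect_true(all(m$distance_bl >= 0))
})

test_that("density maps bin the partner in the focal egocentric frame", {
  # single frame, partner exactly 1 BL ahead: one bin with all the mass
  ev <- make_event(0, 0, 0, 7.75, bl_f = 8, bl_m = 7.5,
                   f_heading = pi / 2, m_heading = pi / 2)
  dm <- density_map(ev, "F", extent_bl = 2, bin_size_bl = 0.1)
  expect_equal(sum(dm$grid), 1)
  expect_equal(sum(dm$grid > 0), 1)
  hit <- which(dm$grid > 0, arr.ind = TRUE)
  mids <- head(dm$breaks, -1) + 0.05
  expect_equal(mids[hit[1, "col"]], 0.05, tolerance = 1e-9)  # x ~ 0
  expect_equal(mids[hit[1, "row"]], 1.05, tolerance = 1e-9)  # y ~ +1 BL

  # left-right mirrored input gives the left-right mirrored map
  set.seed(9)
  n <- 50
  ev2 <- make_event(runif(n, 0, 20), runif(n, 0, 20),
                    runif(n, 0, 20), runif(n, 0, 20))
  mirror <- function(e) {
    flip <- function(ind) {
      ind$frames$x_mm <- -ind$frames$x_mm
      ind$frames$heading_rad <- (pi - ind$frames$heading_rad) %% (2 * pi)
      ind
    }
    e$female <- flip(e$female); e$male <- flip(e$male); e
  }
  d1 <- density_map(ev2, "F", interacting_only = FALSE)
  d2 <- density_map(mirror(ev2), "F", interacting_only = FALSE)
  expect_equal(d2$grid, d1$grid[, ncol(d1$grid):1], tolerance = 1e-12)

  # natural tandems, male focal: the partner (leader) is ahead
  p <- synth_params(fps = 10, duration_s = 120)
  evs <- lapply(1:5, function(s) downsample(simulate_natural_pair(p, seed = s), 1))
  rel <- unlist(lapply(evs, function(e) {
    m <- pair_metrics(e)
    m$rel_dir_m[m$interacting]
  }))
  expect_gt(mean(rel < pi / 2, na.rm = TRUE), 0.9)   # oracle tally
  dmap <- density_map(evs, "M")
  upper <- dmap$grid[(nrow(dmap$grid) / 2 + 1):nrow(dmap$grid), ]
  expect_gt(sum(upper), 0.9)                          # mass ahead

  far <- make_event(c(0, 1), c(0, 0), c(100, 101), c(100, 100),
                    f_heading = 0, m_heading = 0)
  expect_error(density_map(far), "empty density")
})

test_that("both-trapped counts handle escapes and censoring", {
  mk <- function(n_frames, entry, esc_f = NA, esc_m = NA, id = "e1") {
    make_event(seq_len(n_frames), rep(0, n_frames),
               seq_len(n_frames), rep(1, n_frames),
               condition = "trapped", fps = 1, event_id = id,
               entry_frame = as.integer(entry),
               f_escape_frame = as.integer(esc_f),
               m_escape_frame = as.integer(esc_m))
  }
  # no escapes, full 35-min recordings: numerator = denominator
  evs <- lapply(1:4, function(i) mk(35 * 60, 0, id = paste0("e", i)))
  tc <- trapped_counts(evs, c(10, 20, 30))
  expect_equal(tc$both_trapped, c(4, 4, 4))
  expect_equal(tc$observed, c(4, 4, 4))

  # female escape at 15 min: counts as not-both from 20 min on, observed always
  evs2 <- c(evs, list(mk(15 * 60, 0, esc_f = 15 * 60, id = "esc")))
  tc2 <- trapped_counts(evs2, c(10, 20, 30))
  expect_equal(tc2$both_trapped, c(5, 4, 4))
  expect_equal(tc2$observed, c(5, 5, 5))

  # censored event observed only to 25 min: drops out of the 30-min denominator
  evs3 <- c(evs, list(mk(25 * 60, 0, id = "short")))
  tc3 <- trapped_counts(evs3, c(10, 20, 30))
  expect_equal(tc3$observed, c(5, 5, 4))
  expect_equal(tc3$both_trapped, c(5, 5, 4))

  expect_error(trapped_counts(list(make_event(1:3, 1:3, 1:3, 1:3))),
               "trapped events only")
})
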