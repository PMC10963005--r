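test_that("same seed and parameters reproduce simulations bit for bit", {
  p <- synth_params(fps = 10, duration_s = 30)
  a <- simulate_natural_pair(p, seed = 11)
  b <- simulate_natural_pair(p, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_natural_pair(p, seed = 12)))

  ta <- simulate_trapped_pair(p, seed = 11)
  tb <- simulate_trapped_pair(p, seed = 11)
  expect_identical(ta, tb)

  sa <- skeleton_postures(a, p, seed = 7)
  expect_identical(sa, skeleton_postures(a, p, seed = 7))
})

test_that("zero-noise straight tandem reaches the exact contact fixed point", {
  # no turning, unit gain: the follower occupies the formation point exactly
  p <- synth_params(turn_sd_rad = 1e-12, follower_gain = 1,
                    pos_noise_sd_mm = 0, fps = 10, duration_s = 10)
  ev <- simulate_natural_pair(p, seed = 2)
  f <- ev$female$frames  # leader
  m <- ev$male$frames    # follower
  burn <- 5:nrow(f)
  bl_mean <- (p$body_length_f_mm + p$body_length_m_mm) / 2
  d <- sqrt((f$x_mm - m$x_mm)^2 + (f$y_mm - m$y_mm)^2)
  # unit-gain fixed point: the follower occupies the previous formation
  # point, so it trails by exactly the contact offset plus one leader step
  step <- sqrt(diff(f$x_mm)^2 + diff(f$y_mm)^2)
  expect_equal(d[burn], (p$contact_dist_bl * bl_mean + step)[burn - 1],
               tolerance = 1e-9)
  # follower head sits near the leader's abdomen tip: the same fixed point
  # net of the tip and head offsets along the shared axis
  u <- cbind(cos(f$heading_rad), sin(f$heading_rad))
  tip <- cbind(f$x_mm, f$y_mm) - 0.5 * p$body_length_f_mm * u
  uf <- cbind(cos(m$heading_rad), sin(m$heading_rad))
  head_m <- cbind(m$x_mm, m$y_mm) + 0.4 * p$body_length_m_mm * uf
  gap <- sqrt(rowSums((tip - head_m)^2))
  expected_gap <- d - 0.5 * p$body_length_f_mm - 0.4 * p$body_length_m_mm
  expect_equal(gap[burn], expected_gap[burn], tolerance = 1e-6)
})

test_that("natural tandems place the partner behind the leader at ~2 BL/s", {
  p <- synth_params(fps = 10, duration_s = 120)
  rel_dirs <- c()
  speeds <- c()
  for (s in 1:20) {
    ev <- simulate_natural_pair(p, seed = 100 + s)
    m <- pair_metrics(downsample(ev, 1))
    rel_dirs <- c(rel_dirs, m$rel_dir_f)   # female leads by default
    sp <- speed_bl_s(ev$female, p$fps)     # leader speed at native rate
    speeds <- c(speeds, sp$speed_bl_s)
  }
  expect_lt(abs(mean(rel_dirs, na.rm = TRUE) - pi), 0.2)
  se <- sd(speeds) / sqrt(length(speeds))
  expect_lt(abs(mean(speeds) - p$leader_speed_mean_bl_s), 3 * se)
})

test_that("generated events satisfy the pair-event invariants", {
  p <- synth_params(fps = 10, duration_s = 60)
  for (s in 1:5) {
    for (ev in list(simulate_natural_pair(p, seed = s),
                    simulate_trapped_pair(p, seed = s))) {
      expect_s3_class(ev, "pair_event")
      for (ind in list(ev$female, ev$male)) {
        expect_false(is.unsorted(ind$frames$frame, strictly = TRUE))
        expect_true(all(ind$frames$heading_rad >= 0 &
                          ind$frames$heading_rad < 2 * pi))
      }
      if (ev$condition == "trapped") {
        expect_false(is.na(ev$entry_frame))
        for (esc in c(ev$f_escape_frame, ev$m_escape_frame)) {
          if (!is.na(esc)) expect_gte(esc, ev$entry_frame)
        }
      } else {
        expect_true(is.na(ev$entry_frame))
      }
    }
  }
})

test_that("entrapment slows movement by the trap factor and pairs settle side-by-side", {
  p <- synth_params(fps = 10, duration_s = 300, escape_hazard_per_min = 0)
  ratios <- c()
  dists <- c()
  axis_frac <- c()
  for (s in 1:8) {
    ev <- simulate_trapped_pair(p, seed = 200 + s)
    sp <- speed_bl_s(ev$female, p$fps)  # leader
    pre <- sp$frame < ev$entry_frame
    post <- sp$frame > ev$entry_frame + 60 * p$fps  # settled phase
    ratios <- c(ratios, mean(sp$speed_bl_s[post]) / mean(sp$speed_bl_s[pre]))
    m <- pair_metrics(ev)
    mp <- m[m$frame > ev$entry_frame + 60 * p$fps, ]
    dists <- c(dists, mean(mp$distance_bl))
    axis_frac <- c(axis_frac, mean(pmin(mp$heading_diff,
                                        pi - mp$heading_diff) < 0.5))
  }
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - p$trap_speed_factor), 3 * se + 0.002)
  # settled pairs sit much closer than the 1-BL tandem formation...
  expect_lt(mean(dists), 0.7)
  # ...with headings parallel or antiparallel
  expect_gt(mean(axis_frac), 0.9)
})

test_that("a unit trap factor leaves post-entry speeds at natural levels", {
  p <- synth_params(fps = 10, duration_s = 120, trap_speed_factor = 1,
                    escape_hazard_per_min = 0)
  ev <- simulate_trapped_pair(p, seed = 31)
  sp <- speed_bl_s(ev$female, p$fps)
  post <- sp$speed_bl_s[sp$frame > ev$entry_frame]
  # same per-step speed law as a natural walk
  expect_lt(abs(mean(post) - p$leader_speed_mean_bl_s),
            3 * sd(post) / sqrt(length(post)) + 0.01)
})

test_that("skeleton postures are collinear with exact body lengths at zero noise", {
  p <- synth_params(fps = 10, duration_s = 30, pos_noise_sd_mm = 0)
  ev <- simulate_natural_pair(p, seed = 5)
  post <- skeleton_postures(ev, p, noise_sd_mm = 0)
  w <- tidyr::pivot_wider(post[, c("frame", "bodypart", "x_mm", "y_mm")],
                          names_from = "bodypart",
                          values_from = c("x_mm", "y_mm"))
  d_f <- sqrt((w$x_mm_fHead - w$x_mm_fTip)^2 + (w$y_mm_fHead - w$y_mm_fTip)^2)
  expect_equal(d_f, rep((1.0 - 0.1) * p$body_length_f_mm, nrow(w)),
               tolerance = 1e-9)
  # collinearity: triangle head/pronotum/tip has zero area
  area <- abs((w$x_mm_fPro - w$x_mm_fHead) * (w$y_mm_fTip - w$y_mm_fHead) -
                (w$x_mm_fTip - w$x_mm_fHead) * (w$y_mm_fPro - w$y_mm_fHead)) / 2
  expect_true(all(area < 1e-9))
  # female-led geometry: female tip to male head is the short cross distance
  th <- tip_head_distances(post, p$body_length_f_mm, p$body_length_m_mm)
  burn <- th$frame > 5
  expect_true(all(th$d_fTip_mHead[burn] < th$d_fHead_mTip[burn]))
})
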