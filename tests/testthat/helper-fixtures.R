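# Small programmatic fixtures shared across test files.

# A straight or arbitrary trajectory as a tracked_individual.
make_walk <- function(x, y, sex = "F", bl = 8, heading = NA_real_,
                      id = paste0("walk", sex)) {
  n <- length(x)
  tracked_individual(id, sex, bl,
                     tibble::tibble(frame = 0:(n - 1), x_mm = x, y_mm = y,
                                    heading_rad = rep(heading, length.out = n)))
}

# A pair event from two coordinate sets.
make_event <- function(fx, fy, mx, my, condition = "natural", fps = 1,
                       bl_f = 8, bl_m = 7.5, pair_id = "p1", event_id = "e1",
                       f_heading = NA_real_, m_heading = NA_real_, ...) {
  pair_event(pair_id, event_id, condition, fps,
             female = make_walk(fx, fy, "F", bl_f, f_heading),
             male = make_walk(mx, my, "M", bl_m, m_heading), ...)
}

# An independent-walk "pair": female and male drawn from two unrelated
# simulations, so any pairing structure is broken by construction.
make_independent_pair <- function(seed, params, pair_id = "ind") {
  a <- simulate_natural_pair(params, leader_sex = "F", seed = seed,
                             pair_id = pair_id, event_id = "a")
  b <- simulate_natural_pair(params, leader_sex = "M", seed = seed + 5000L,
                             pair_id = pair_id, event_id = "b")
  pair_event(pair_id, "e1", "natural", params$fps,
             female = a$female, male = b$male)
}

# Long-form posture table from named body-part coordinates.
make_posture <- function(coords, frame = 0) {
  tibble::tibble(frame = frame,
                 bodypart = names(coords),
                 x_mm = unname(vapply(coords, `[`, numeric(1), 1)),
                 y_mm = unname(vapply(coords, `[`, numeric(1), 2)),
                 likelihood = 1)
}

# Brute-force per-frame metric oracle: scalar trigonometry, no shared code
# with pair_metrics().
naive_frame_metrics <- function(fx, fy, fth, mx, my, mth, bl_f, bl_m) {
  d_mm <- sqrt((fx - mx)^2 + (fy - my)^2)
  ang <- function(hx, hy, vx, vy) {
    # unsigned angle between heading unit vector and bearing vector
    acos(pmin(pmax((hx * vx + hy * vy) /
                     sqrt(vx^2 + vy^2), -1), 1))
  }
  list(distance_bl = d_mm / ((bl_f + bl_m) / 2),
       rel_dir_f = ang(cos(fth), sin(fth), mx - fx, my - fy),
       rel_dir_m = ang(cos(mth), sin(mth), fx - mx, fy - my),
       heading_diff = acos(pmin(pmax(cos(fth) * cos(mth) +
                                       sin(fth) * sin(mth), -1), 1)),
       interacting = d_mm < (bl_f + bl_m))
}

# Labelled features from simulated female-led tandems; leaders are the
# female-focal rows, followers the male-focal rows.
tandem_features <- function(n_events, seed0, p) {
  dplyr::bind_rows(lapply(seq_len(n_events), function(i) {
    ev <- simulate_natural_pair(p, seed = seed0 + i,
                                pair_id = paste0("t", i))
    post <- skeleton_postures(ev, p, seed = seed0 + 100 + i)
    nb <- (p$body_length_f_mm + p$body_length_m_mm) / 2
    dplyr::bind_rows(
      relative_head_features(post, "F", nb, role = "leader",
                             source_id = paste0("t", i)),
      relative_head_features(post, "M", nb, role = "follower",
                             source_id = paste0("t", i)))
  }))
}

# Enumeration oracle for the exact rank-sum test: all C(n1+n2, n1) label
# assignments of the pooled sample.
enum_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  W_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  ws <- apply(combn(n1 + n2, n1), 2, function(ii) {
    xx <- pooled[ii]; yy <- pooled[-ii]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  eps <- 1e-9
  list(W = W_obs,
       p = min(1, 2 * min(mean(ws <= W_obs + eps), mean(ws >= W_obs - eps))))
}
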