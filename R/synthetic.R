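#' Parameters for the synthetic tandem generator
#'
#' Bundles every knob of the synthetic trajectory/posture generator with
#' defaults chosen to emulate the observed kinematics of termite tandem
#' running: leaders move at about 2 body lengths per second in natural
#' tandems, trapped animals at about 3% of that, and the follower keeps its
#' head at the leader's abdomen tip. See the package vignette for the
#' rationale behind each default.
#'
#' @param leader_speed_mean_bl_s,leader_speed_sd Mean and SD of the leader's
#'   per-step speed draw, in body lengths per second (truncated at 0).
#' @param turn_sd_rad Heading-increment SD per square-root second; the
#'   per-step SD at frame rate `fps` is `turn_sd_rad / sqrt(fps)`.
#' @param contact_dist_bl Centroid-to-centroid formation offset the follower
#'   pursues, in mean body lengths, measured backwards along the leader's
#'   heading. The default 1.0 places the follower's head at the leader's
#'   abdomen tip given the default body-part proportions.
#' @param follower_gain Per-step proportional gain of the follower's pursuit,
#'   in (0, 1].
#' @param trap_speed_factor Multiplier applied to speed and turning once an
#'   animal is on the sticky patch, in (0, 1].
#' @param escape_hazard_per_min Constant per-individual hazard of escaping
#'   the sticky patch, per minute.
#' @param heading_mix_w Probability that a trapped follower settles heading
#'   the same way as the leader (otherwise opposite).
#' @param pos_noise_sd_mm Isotropic positional measurement noise SD in mm,
#'   added to centroid tracks.
#' @param posture_noise_sd_mm Isotropic landmark noise SD in mm for skeleton
#'   postures, standing in for pose-estimation error and within-body posture
#'   variation.
#' @param body_length_f_mm,body_length_m_mm Female and male body lengths.
#' @param proportions Named fractions of body length (from the anterior end)
#'   at which the tracked head middle, pronotum border and abdomen tip lie;
#'   must be increasing. The centroid sits at fraction 0.5.
#' @param fps Simulation/recording frame rate.
#' @param duration_s Recorded duration in seconds (for trapped events, the
#'   post-entry duration).
#' @param seed Default integer seed; individual simulators accept an override.
#'
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(leader_speed_mean_bl_s = 2.0,
                         leader_speed_sd = 0.5,
                         turn_sd_rad = 0.3,
                         contact_dist_bl = 1.0,
                         follower_gain = 0.8,
                         trap_speed_factor = 0.03,
                         escape_hazard_per_min = 0.0212,
                         heading_mix_w = 0.5,
                         pos_noise_sd_mm = 0,
                         posture_noise_sd_mm = 0.4,
                         body_length_f_mm = 8.0,
                         body_length_m_mm = 7.5,
                         proportions = c(head = 0.1, pronotum = 0.3, tip = 1.0),
                         fps = 30,
                         duration_s = 1800,
                         seed = 1L) {
  p <- list(leader_speed_mean_bl_s = leader_speed_mean_bl_s,
            leader_speed_sd = leader_speed_sd,
            turn_sd_rad = turn_sd_rad,
            contact_dist_bl = contact_dist_bl,
            follower_gain = follower_gain,
            trap_speed_factor = trap_speed_factor,
            escape_hazard_per_min = escape_hazard_per_min,
            heading_mix_w = heading_mix_w,
            pos_noise_sd_mm = pos_noise_sd_mm,
            posture_noise_sd_mm = posture_noise_sd_mm,
            body_length_f_mm = body_length_f_mm,
            body_length_m_mm = body_length_m_mm,
            proportions = proportions,
            fps = fps, duration_s = duration_s, seed = as.integer(seed))
  pos <- c("leader_speed_mean_bl_s", "leader_speed_sd", "turn_sd_rad",
           "contact_dist_bl", "follower_gain", "body_length_f_mm",
           "body_length_m_mm", "fps", "duration_s")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || is.na(p[[nm]]) ||
        p[[nm]] <= 0) {
      abort(paste0("`", nm, "` must be a single positive number."))
    }
  }
  if (p$follower_gain > 1) abort("`follower_gain` must lie in (0, 1].")
  if (p$trap_speed_factor <= 0 || p$trap_speed_factor > 1) {
    abort("`trap_speed_factor` must lie in (0, 1].")
  }
  if (p$escape_hazard_per_min < 0) {
    abort("`escape_hazard_per_min` must be nonnegative.")
  }
  if (p$heading_mix_w < 0 || p$heading_mix_w > 1) {
    abort("`heading_mix_w` must lie in [0, 1].")
  }
  if (p$pos_noise_sd_mm < 0) abort("`pos_noise_sd_mm` must be nonnegative.")
  if (p$posture_noise_sd_mm < 0) abort("`posture_noise_sd_mm` must be nonnegative.")
  pr <- p$proportions
  if (!all(c("head", "pronotum", "tip") %in% names(pr))) {
    abort("`proportions` must have entries head, pronotum, tip.")
  }
  if (!(pr[["head"]] < pr[["pronotum"]] && pr[["pronotum"]] < pr[["tip"]])) {
    abort("`proportions` must be ordered head < pronotum < tip.")
  }
  if (any(pr < 0 | pr > 1)) abort("`proportions` must lie in [0, 1].")
  structure(p, class = "synth_params")
}

# Truncated-at-zero normal draws by rejection (vectorised, deterministic).
rtnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Forward-difference headings: direction of displacement t -> t+1, carried
# forward over zero-length steps; first heading given as fallback.
displacement_headings <- function(x, y, fallback) {
  n <- length(x)
  dx <- diff(x); dy <- diff(y)
  th <- rep(NA_real_, n)
  moved <- sqrt(dx^2 + dy^2) > 0
  th[which(moved)] <- wrap_angle(atan2(dy[moved], dx[moved]))
  if (is.na(th[1])) th[1] <- wrap_angle(fallback)
  for (i in seq_len(n - 1)) if (is.na(th[i + 1])) th[i + 1] <- th[i]
  th
}

#' Simulate a natural tandem run
#'
#' The leader performs a correlated random walk: per-step speed drawn from a
#' truncated normal, heading increments Gaussian. The follower pursues the
#' formation point `contact_dist_bl` mean body lengths behind the leader's
#' centroid along the leader's heading with proportional gain, which places
#' its head at the leader's abdomen tip under the default body-part
#' proportions; its heading is its displacement direction. Optional isotropic
#' positional noise is added last.
#'
#' @param params A [synth_params()] object.
#' @param leader_sex `"F"` (the leading sex in *Coptotermes formosanus*) or
#'   `"M"`.
#' @param seed Integer seed overriding `params$seed`.
#' @param pair_id,event_id Identifiers for the returned event.
#'
#' @return A [pair_event()] with `condition = "natural"`.
#' @export
simulate_natural_pair <- function(params = synth_params(), leader_sex = "F",
                                  seed = params$seed, pair_id = "synthP",
                                  event_id = "e1") {
  stopifnot(inherits(params, "synth_params"))
  leader_sex <- match.arg(leader_sex, c("F", "M"))
  n <- floor(params$duration_s * params$fps) + 1
  if (n < 2) abort("duration_s * fps must give at least 2 frames.")
  set.seed(seed)

  bl <- c(F = params$body_length_f_mm, M = params$body_length_m_mm)
  bl_lead <- bl[[leader_sex]]
  bl_mean <- mean(bl)
  fps <- params$fps

  theta0 <- runif(1, 0, 2 * pi)
  speeds <- rtnorm0(n - 1, params$leader_speed_mean_bl_s,
                    params$leader_speed_sd)
  turns <- rnorm(n - 1, 0, params$turn_sd_rad / sqrt(fps))
  theta <- wrap_angle(theta0 + c(0, cumsum(turns)))
  step <- speeds * bl_lead / fps
  lx <- c(0, cumsum(step * cos(theta[-n])))
  ly <- c(0, cumsum(step * sin(theta[-n])))

  # Formation point the follower chases, one contact offset behind the leader.
  off <- params$contact_dist_bl * bl_mean
  tx <- lx - off * cos(theta)
  ty <- ly - off * sin(theta)
  g <- params$follower_gain
  # c[t+1] = (1 - g) c[t] + g T[t]  -- linear recursion, run as a filter.
  fx <- c(tx[1], stats::filter(g * tx[-n], 1 - g, method = "recursive",
                               init = tx[1]))
  fy <- c(ty[1], stats::filter(g * ty[-n], 1 - g, method = "recursive",
                               init = ty[1]))

  if (params$pos_noise_sd_mm > 0) {
    lx <- lx + rnorm(n, 0, params$pos_noise_sd_mm)
    ly <- ly + rnorm(n, 0, params$pos_noise_sd_mm)
    fx <- fx + rnorm(n, 0, params$pos_noise_sd_mm)
    fy <- fy + rnorm(n, 0, params$pos_noise_sd_mm)
  }
  theta_f <- displacement_headings(fx, fy, theta[1])

  frames_lead <- tibble::tibble(frame = 0:(n - 1), x_mm = lx, y_mm = ly,
                                heading_rad = theta)
  frames_foll <- tibble::tibble(frame = 0:(n - 1), x_mm = fx, y_mm = fy,
                                heading_rad = theta_f)
  follower_sex <- setdiff(c("F", "M"), leader_sex)
  mk <- function(sex, frames) {
    tracked_individual(paste(pair_id, event_id, sex, sep = "_"), sex,
                       bl[[sex]], frames)
  }
  inds <- list()
  inds[[leader_sex]] <- mk(leader_sex, frames_lead)
  inds[[follower_sex]] <- mk(follower_sex, frames_foll)
  pair_event(pair_id, event_id, "natural", fps,
             female = inds$F, male = inds$M)
}

# Arena / sticky-patch geometry (mm): axis-aligned 80 mm square patch centred
# in a 221 x 114 mm arena, mirroring the taphonomic experiment.
ARENA_W <- 221
ARENA_H <- 114
PATCH_SIDE <- 80
# Settling slot of a trapped follower relative to the stuck leader, in mean
# body lengths: displaced sideways by about half a body width and rearward by
# just under half a body length, so the bodies lie side-by-side with the
# follower's head next to the leader's abdomen region -- trapped pairs keep
# the head-to-abdomen-tip signature of the tandem even when parallel.
SIDE_OFFSET_BL <- 0.15
AXIAL_SETTLE_BL <- 0.45
# How far past the patch boundary the leader advances before the surface
# holds it for good; exceeds one body length so the follower is drawn onto
# the patch too, as observed in entrapment events.
STICK_DEPTH_MM <- 12

in_patch <- function(x, y) {
  cx <- ARENA_W / 2; cy <- ARENA_H / 2; h <- PATCH_SIDE / 2
  abs(x - cx) <= h & abs(y - cy) <= h
}

#' Simulate a sticky-trap entrapment event
#'
#' The pair approaches the sticky patch in natural tandem formation (the
#' leader's heading is weakly steered towards the patch so that every
#' simulated event reaches it). Once an animal's centroid is on the patch its
#' speed and turning are multiplied by `trap_speed_factor`. The follower
#' keeps pursuing the leader; once the follower itself is trapped it settles
#' beside the leader at a lateral offset of about half a body width, with its
#' heading drawn parallel to the leader's (probability `heading_mix_w`) or
#' antiparallel. Each individual escapes with a constant exponential hazard
#' `escape_hazard_per_min`; the recording is truncated at the first escape,
#' and unescaped animals are right-censored at the recording end.
#'
#' @inheritParams simulate_natural_pair
#' @return A [pair_event()] with `condition = "trapped"`, `entry_frame` set to
#'   the leader's first on-patch frame, and escape frames set or censored.
#' @export
simulate_trapped_pair <- function(params = synth_params(), leader_sex = "F",
                                  seed = params$seed, pair_id = "synthP",
                                  event_id = "e1") {
  stopifnot(inherits(params, "synth_params"))
  leader_sex <- match.arg(leader_sex, c("F", "M"))
  fps <- params$fps
  n_post <- floor(params$duration_s * fps) + 1
  if (n_post < 2) abort("duration_s * fps must give at least 2 frames.")
  set.seed(seed)

  bl <- c(F = params$body_length_f_mm, M = params$body_length_m_mm)
  bl_lead <- bl[[leader_sex]]
  bl_foll <- bl[[setdiff(c("F", "M"), leader_sex)]]
  bl_mean <- mean(bl)
  off <- params$contact_dist_bl * bl_mean
  g <- params$follower_gain
  fac <- params$trap_speed_factor
  turn_sd <- params$turn_sd_rad / sqrt(fps)
  patch_cx <- ARENA_W / 2; patch_cy <- ARENA_H / 2

  # Pre-entry approach budget; steering makes entry near-certain well before.
  n_pre_max <- as.integer(60 * fps)
  n_max <- n_pre_max + n_post
  # Pre-draw all randomness so the per-frame loop is deterministic arithmetic.
  v_lead <- rtnorm0(n_max, params$leader_speed_mean_bl_s,
                    params$leader_speed_sd) * bl_lead / fps
  v_foll <- rtnorm0(n_max, params$leader_speed_mean_bl_s,
                    params$leader_speed_sd) * bl_foll / fps
  turns <- rnorm(n_max, 0, turn_sd)
  # In-place jitter of stuck animals: step directions follow a slowly mixing
  # random walk on the circle (decorrelation ~1 s) so that speed measured at
  # 1 FPS stays close to the trapped speed, while an anchor pull (below)
  # keeps the centroid at the sticking point.
  jig_sd <- sqrt(2 / fps)
  jig_l <- wrap_angle(runif(1, 0, 2 * pi) + cumsum(rnorm(n_max, 0, jig_sd)))
  jig_f <- wrap_angle(runif(1, 0, 2 * pi) + cumsum(rnorm(n_max, 0, jig_sd)))
  settle_wob <- rnorm(n_max, 0, 0.05)
  same_dir <- runif(1) < params$heading_mix_w
  side <- sample(c(-1, 1), 1)
  esc_lead_min <- if (params$escape_hazard_per_min > 0)
    rexp(1, params$escape_hazard_per_min) else Inf
  esc_foll_min <- if (params$escape_hazard_per_min > 0)
    rexp(1, params$escape_hazard_per_min) else Inf

  # Start 30 mm outside the patch edge, headed at the patch centre.
  start_x <- patch_cx - PATCH_SIDE / 2 - 30
  start_y <- patch_cy
  lx <- ly <- fx <- fy <- th_l <- th_f <- numeric(n_max)
  lx[1] <- start_x; ly[1] <- start_y
  th_l[1] <- atan2(patch_cy - start_y, patch_cx - start_x)
  fx[1] <- lx[1] - off * cos(th_l[1])
  fy[1] <- ly[1] - off * sin(th_l[1])
  th_f[1] <- th_l[1]

  # An animal entering the patch is not held instantly: the leader advances
  # STICK_DEPTH_MM past the boundary (dragging the follower onto the patch)
  # before the surface holds it for good.
  entry_i <- NA_integer_    # leader's first on-patch index (1-based)
  lead_stuck <- FALSE       # absorbing
  foll_on_patch <- FALSE    # absorbing: slowed from first patch contact
  settling <- FALSE         # follower en route to / at the side-by-side slot
  settle_heading <- NA_real_
  anchor <- c(NA_real_, NA_real_)

  # Anchored trapped step: a step of length exactly `cap` (so measured speed
  # equals the trapped speed) in a direction blending the pull towards the
  # anchor with slowly-mixing jitter; the pull dominates when displaced, the
  # jitter when at the anchor, giving bounded in-place wiggling.
  anchored_step <- function(cx, cy, ax, ay, cap, jig) {
    dx <- g * (ax - cx); dy <- g * (ay - cy)
    len <- sqrt(dx^2 + dy^2)
    if (len < cap) {
      rem <- cap - len
      dx <- dx + rem * cos(jig); dy <- dy + rem * sin(jig)
      len <- sqrt(dx^2 + dy^2)
    }
    if (len == 0) return(c(cap * cos(jig), cap * sin(jig)))
    c(dx * cap / len, dy * cap / len)
  }

  i <- 1
  while (i < n_max) {
    on_patch <- in_patch(lx[i], ly[i])
    if (is.na(entry_i) && on_patch) entry_i <- i
    if (!lead_stuck && on_patch) {
      h <- PATCH_SIDE / 2
      depth <- min(h - abs(lx[i] - patch_cx), h - abs(ly[i] - patch_cy))
      if (depth >= STICK_DEPTH_MM) {
        lead_stuck <- TRUE
        anchor <- c(lx[i], ly[i])
      }
    }
    if (!is.na(entry_i) && i - entry_i >= n_post - 1) break
    if (is.na(entry_i) && i > n_pre_max) {
      abort("leader failed to reach the sticky patch within the approach budget")
    }

    # Leader: CRW steered towards the patch centre until stuck; once stuck,
    # body orientation nearly frozen (turning damped by trap_speed_factor)
    # and the centroid jitters at trapped speed around the sticking point.
    if (lead_stuck) {
      th_l[i + 1] <- wrap_angle(th_l[i] + turns[i] * fac)
      st <- anchored_step(lx[i], ly[i], anchor[1], anchor[2],
                          v_lead[i] * fac, jig_l[i])
      lx[i + 1] <- lx[i] + st[1]
      ly[i + 1] <- ly[i] + st[2]
    } else {
      bearing <- atan2(patch_cy - ly[i], patch_cx - lx[i])
      corr <- wrap_angle(bearing - th_l[i] + pi) - pi
      th_l[i + 1] <- wrap_angle(th_l[i] + 0.2 * corr + turns[i])
      lx[i + 1] <- lx[i] + v_lead[i] * cos(th_l[i + 1])
      ly[i + 1] <- ly[i] + v_lead[i] * sin(th_l[i + 1])
    }

    # Follower: natural-speed pursuit of the formation point until it is on
    # the patch itself (then slowed); once the leader is stuck it makes for
    # the side-by-side slot beside the leader and settles there with a drawn
    # parallel or antiparallel heading.
    if (!foll_on_patch && in_patch(fx[i], fy[i])) foll_on_patch <- TRUE
    if (!settling && lead_stuck && foll_on_patch) {
      settling <- TRUE
      settle_heading <- if (same_dir) th_l[i] else th_l[i] + pi
    }
    cap <- if (foll_on_patch) v_foll[i] * fac else v_foll[i]
    if (settling) {
      perp <- th_l[i] + pi / 2
      ax <- lx[i] - AXIAL_SETTLE_BL * bl_mean * cos(th_l[i]) +
        side * SIDE_OFFSET_BL * bl_mean * cos(perp)
      ay <- ly[i] - AXIAL_SETTLE_BL * bl_mean * sin(th_l[i]) +
        side * SIDE_OFFSET_BL * bl_mean * sin(perp)
      st <- anchored_step(fx[i], fy[i], ax, ay, cap, jig_f[i])
      dx <- st[1]; dy <- st[2]
    } else {
      dx <- g * (lx[i] - off * cos(th_l[i]) - fx[i])
      dy <- g * (ly[i] - off * sin(th_l[i]) - fy[i])
      len <- sqrt(dx^2 + dy^2)
      if (len > cap && len > 0) { dx <- dx * cap / len; dy <- dy * cap / len }
    }
    fx[i + 1] <- fx[i] + dx
    fy[i + 1] <- fy[i] + dy
    th_f[i + 1] <- if (settling) {
      wrap_angle(settle_heading + settle_wob[i])
    } else if (dx != 0 || dy != 0) {
      wrap_angle(atan2(dy, dx))
    } else {
      th_f[i]
    }
    i <- i + 1
  }
  n <- i
  entry_frame <- entry_i - 1L  # 0-based

  esc_frame <- function(mins) {
    f <- entry_frame + floor(mins * 60 * fps)
    if (is.finite(f) && f <= n - 1) as.integer(f) else NA_integer_
  }
  esc_lead <- esc_frame(esc_lead_min)
  esc_foll <- esc_frame(esc_foll_min)
  first_esc <- suppressWarnings(min(esc_lead, esc_foll, na.rm = TRUE))
  if (is.finite(first_esc)) {
    n <- first_esc + 1L  # truncate recording at the first escape
    esc_lead <- if (!is.na(esc_lead) && esc_lead <= n - 1) esc_lead else NA_integer_
    esc_foll <- if (!is.na(esc_foll) && esc_foll <= n - 1) esc_foll else NA_integer_
  }

  keep <- seq_len(n)
  lx <- lx[keep]; ly <- ly[keep]; fx <- fx[keep]; fy <- fy[keep]
  th_l <- th_l[keep]; th_f <- th_f[keep]
  if (params$pos_noise_sd_mm > 0) {
    lx <- lx + rnorm(n, 0, params$pos_noise_sd_mm)
    ly <- ly + rnorm(n, 0, params$pos_noise_sd_mm)
    fx <- fx + rnorm(n, 0, params$pos_noise_sd_mm)
    fy <- fy + rnorm(n, 0, params$pos_noise_sd_mm)
  }

  follower_sex <- setdiff(c("F", "M"), leader_sex)
  mk <- function(sex, x, y, th) {
    tracked_individual(paste(pair_id, event_id, sex, sep = "_"), sex,
                       bl[[sex]],
                       tibble::tibble(frame = 0:(n - 1), x_mm = x, y_mm = y,
                                      heading_rad = wrap_angle(th)))
  }
  inds <- list()
  inds[[leader_sex]] <- mk(leader_sex, lx, ly, th_l)
  inds[[follower_sex]] <- mk(follower_sex, fx, fy, th_f)
  esc <- list(); esc[[leader_sex]] <- esc_lead; esc[[follower_sex]] <- esc_foll
  pair_event(pair_id, event_id, "trapped", fps,
             female = inds$F, male = inds$M,
             entry_frame = entry_frame,
             f_escape_frame = esc$F, m_escape_frame = esc$M)
}

#' Generate skeleton postures from a pair event
#'
#' Places the six tracked body points (head middle, pronotum border, abdomen
#' tip of each sex) collinearly along each animal's heading axis through its
#' centroid, at the body-length fractions in `params$proportions` (centroid at
#' fraction 0.5), plus isotropic Gaussian noise of SD `noise_sd_mm`.
#' All likelihoods are 1.
#'
#' @param event A [pair_event()] whose frames carry headings (estimated with
#'   [estimate_heading()] if missing).
#' @param params A [synth_params()] (for proportions).
#' @param noise_sd_mm Landmark noise SD; defaults to
#'   `params$posture_noise_sd_mm`.
#' @param seed Integer seed for the noise draws.
#'
#' @return A long posture tibble (`frame`, `bodypart`, `x_mm`, `y_mm`,
#'   `likelihood`) as returned by [read_posture_table()].
#' @export
skeleton_postures <- function(event, params = synth_params(),
                              noise_sd_mm = params$posture_noise_sd_mm,
                              seed = params$seed) {
  stopifnot(inherits(event, "pair_event"))
  set.seed(seed)
  pr <- params$proportions
  one <- function(ind, prefix) {
    fr <- ind$frames
    if (anyNA(fr$heading_rad)) {
      fr <- estimate_heading(ind)$frames
    }
    u <- heading_vector(fr$heading_rad)
    pieces <- lapply(c(head = "Head", pronotum = "Pro", tip = "Tip"),
                     function(suffix) suffix)
    out <- lapply(names(pieces), function(part) {
      d <- (0.5 - pr[[part]]) * ind$body_length_mm
      tibble::tibble(frame = fr$frame, bodypart = paste0(prefix, pieces[[part]]),
                     x_mm = fr$x_mm + d * u[, 1],
                     y_mm = fr$y_mm + d * u[, 2],
                     likelihood = 1)
    })
    dplyr::bind_rows(out)
  }
  long <- dplyr::bind_rows(one(event$female, "f"), one(event$male, "m"))
  if (noise_sd_mm > 0) {
    long$x_mm <- long$x_mm + rnorm(nrow(long), 0, noise_sd_mm)
    long$y_mm <- long$y_mm + rnorm(nrow(long), 0, noise_sd_mm)
  }
  long[order(long$frame, match(long$bodypart, BODYPART_LABELS)), ]
}
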