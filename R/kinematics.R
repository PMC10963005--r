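#' Estimate headings from displacements
#'
#' Fills missing headings with the direction of the forward displacement
#' (frame t to t+1) whenever that displacement is at least `min_step_mm`
#' long; shorter steps carry the last valid heading forward, and leading
#' undefined headings are back-filled from the first valid one. Stored
#' headings are kept.
#'
#' @param individual A [tracked_individual()].
#' @param min_step_mm Minimum displacement length to trust as a heading.
#' @return The individual with `heading_rad` filled for every frame.
#' @export
estimate_heading <- function(individual, min_step_mm = 0) {
  stopifnot(inherits(individual, "tracked_individual"))
  fr <- individual$frames
  n <- nrow(fr)
  if (n < 2) abort("need at least 2 frames to estimate headings.")
  th <- fr$heading_rad
  dx <- diff(fr$x_mm); dy <- diff(fr$y_mm)
  len <- sqrt(dx^2 + dy^2)
  est <- ifelse(len >= pmax(min_step_mm, .Machine$double.eps),
                wrap_angle(atan2(dy, dx)), NA_real_)
  miss <- is.na(th)
  th[miss & c(!is.na(est), FALSE)] <- est[miss[-n] & !is.na(est)]
  # carry forward over still-missing frames
  for (i in seq_len(n - 1)) if (is.na(th[i + 1])) th[i + 1] <- th[i]
  # back-fill leading gap
  first_ok <- which(!is.na(th))[1]
  if (is.na(first_ok)) abort("heading unresolvable: no displacement reaches min_step_mm.")
  if (first_ok > 1) th[seq_len(first_ok - 1)] <- th[first_ok]
  individual$frames$heading_rad <- th
  individual
}

#' Per-frame speed in body lengths per second
#'
#' Forward-difference speed: `||pos(t+1) - pos(t)|| * fps / body_length_mm`.
#' The last frame has no forward difference and is dropped.
#'
#' @param individual A [tracked_individual()].
#' @param fps Frame rate the frames are sampled at.
#' @param body_length_mm Normalising body length; defaults to the
#'   individual's own.
#' @return A tibble with columns `frame` and `speed_bl_s`.
#' @export
speed_bl_s <- function(individual, fps,
                       body_length_mm = individual$body_length_mm) {
  stopifnot(inherits(individual, "tracked_individual"))
  if (!is.numeric(body_length_mm) || body_length_mm <= 0) {
    abort("`body_length_mm` must be positive.")
  }
  fr <- individual$frames
  if (nrow(fr) < 2) abort("need at least 2 frames to compute speed.")
  d <- sqrt(diff(fr$x_mm)^2 + diff(fr$y_mm)^2)
  tibble::tibble(frame = fr$frame[-nrow(fr)],
                 speed_bl_s = d * fps / body_length_mm)
}

#' Direction of a partner relative to a focal heading
#'
#' Unsigned angle in `[0, pi]` between the focal animal's heading vector and
#' the bearing from the focal to the partner: 0 means the partner is directly
#' ahead, `pi` directly behind. Vectorised; coincident positions give `NA`.
#'
#' @param focal_x,focal_y,partner_x,partner_y Coordinates in mm.
#' @param focal_heading Focal heading(s), radians CCW from +x.
#' @return Numeric vector of angles in `[0, pi]`.
#' @export
relative_direction <- function(focal_x, focal_y, focal_heading,
                               partner_x, partner_y) {
  bearing <- atan2(partner_y - focal_y, partner_x - focal_x)
  out <- unsigned_angle_diff(focal_heading, bearing)
  out[partner_x == focal_x & partner_y == focal_y] <- NA_real_
  out
}

#' Per-frame spatial-organisation metrics for a pair event
#'
#' For every frame shared by the female and male tracks computes the
#' centroid distance in body lengths (normalised by the mean of the two body
#' lengths), the direction of the partner relative to each animal's heading,
#' the unsigned heading difference, forward-difference speeds, and the
#' interaction flag. A frame is *interacting* when the raw distance is
#' strictly less than the sum of the two body lengths ("twice a termite body
#' length"), the conservative reach of tandem contact.
#'
#' @param event A [pair_event()]; headings are estimated from displacements
#'   where missing.
#' @param min_step_mm Passed to [estimate_heading()].
#' @return A tibble of per-frame metrics (`frame`, `distance_bl`,
#'   `rel_dir_f`, `rel_dir_m`, `heading_diff`, `speed_f_bl_s`,
#'   `speed_m_bl_s`, `interacting`).
#' @export
pair_metrics <- function(event, min_step_mm = 0) {
  stopifnot(inherits(event, "pair_event"))
  f <- if (anyNA(event$female$frames$heading_rad)) {
    estimate_heading(event$female, min_step_mm)
  } else event$female
  m <- if (anyNA(event$male$frames$heading_rad)) {
    estimate_heading(event$male, min_step_mm)
  } else event$male

  common <- intersect(f$frames$frame, m$frames$frame)
  if (length(common) == 0) abort("female and male tracks share no frames.")
  ff <- f$frames[match(common, f$frames$frame), ]
  mf <- m$frames[match(common, m$frames$frame), ]

  dist_mm <- sqrt((ff$x_mm - mf$x_mm)^2 + (ff$y_mm - mf$y_mm)^2)
  bl_mean <- mean_body_length(event)
  thresh_mm <- event$female$body_length_mm + event$male$body_length_mm

  sp <- function(x, y) {
    s <- c(sqrt(diff(x)^2 + diff(y)^2) * event$fps, NA_real_)
    s
  }
  tibble::tibble(
    frame = common,
    distance_bl = dist_mm / bl_mean,
    rel_dir_f = relative_direction(ff$x_mm, ff$y_mm, ff$heading_rad,
                                   mf$x_mm, mf$y_mm),
    rel_dir_m = relative_direction(mf$x_mm, mf$y_mm, mf$heading_rad,
                                   ff$x_mm, ff$y_mm),
    heading_diff = unsigned_angle_diff(ff$heading_rad, mf$heading_rad),
    speed_f_bl_s = sp(ff$x_mm, ff$y_mm) / event$female$body_length_mm,
    speed_m_bl_s = sp(mf$x_mm, mf$y_mm) / event$male$body_length_mm,
    interacting = dist_mm < thresh_mm
  )
}

#' Egocentric partner density map
#'
#' Translates and rotates every (by default, interacting) frame into the
#' focal animal's reference frame — focal centroid at the origin, heading
#' pointing up (+y) — expresses the partner position in body lengths, bins it
#' on a square grid, pools across events and normalises the grid to sum 1.
#'
#' @param events List of [pair_event()] objects.
#' @param focal_sex `"F"` or `"M"`: which animal defines the reference frame.
#' @param extent_bl Half-width of the map in body lengths.
#' @param bin_size_bl Bin size in body lengths.
#' @param interacting_only Keep only frames within the interaction distance.
#' @param min_step_mm Passed to heading estimation.
#' @return An object of class `density_map`: a list with the normalised
#'   `grid` (rows = y from bottom to top, columns = x), bin edges, counts and
#'   metadata.
#' @export
density_map <- function(events, focal_sex = c("F", "M"), extent_bl = 2,
                        bin_size_bl = 0.1, interacting_only = TRUE,
                        min_step_mm = 0) {
  focal_sex <- match.arg(focal_sex)
  if (inherits(events, "pair_event")) events <- list(events)
  breaks <- seq(-extent_bl, extent_bl, by = bin_size_bl)
  nb <- length(breaks) - 1
  counts <- matrix(0, nrow = nb, ncol = nb)
  n_obs <- 0L
  for (ev in events) {
    f <- if (anyNA(ev$female$frames$heading_rad)) {
      estimate_heading(ev$female, min_step_mm)
    } else ev$female
    m <- if (anyNA(ev$male$frames$heading_rad)) {
      estimate_heading(ev$male, min_step_mm)
    } else ev$male
    foc <- if (focal_sex == "F") f else m
    par <- if (focal_sex == "F") m else f
    common <- intersect(foc$frames$frame, par$frames$frame)
    if (length(common) == 0) next
    pf <- foc$frames[match(common, foc$frames$frame), ]
    pp <- par$frames[match(common, par$frames$frame), ]
    dxm <- pp$x_mm - pf$x_mm
    dym <- pp$y_mm - pf$y_mm
    if (interacting_only) {
      keep <- sqrt(dxm^2 + dym^2) <
        (ev$female$body_length_mm + ev$male$body_length_mm)
      dxm <- dxm[keep]; dym <- dym[keep]; hd <- pf$heading_rad[keep]
    } else {
      hd <- pf$heading_rad
    }
    if (length(dxm) == 0) next
    # rotate so the focal heading maps onto +y
    a <- pi / 2 - hd
    bl_mean <- mean_body_length(ev)
    rx <- (cos(a) * dxm - sin(a) * dym) / bl_mean
    ry <- (sin(a) * dxm + cos(a) * dym) / bl_mean
    inside <- rx >= -extent_bl & rx <= extent_bl &
      ry >= -extent_bl & ry <= extent_bl
    if (!any(inside)) next
    ix <- pmin(pmax(findInterval(rx[inside], breaks,
                                 rightmost.closed = TRUE), 1L), nb)
    iy <- pmin(pmax(findInterval(ry[inside], breaks,
                                 rightmost.closed = TRUE), 1L), nb)
    for (k in seq_along(ix)) counts[iy[k], ix[k]] <- counts[iy[k], ix[k]] + 1
    n_obs <- n_obs + length(ix)
  }
  if (n_obs == 0) abort("empty density: no frames to bin (after filtering).")
  structure(list(grid = counts / sum(counts), counts = counts,
                 breaks = breaks, focal_sex = focal_sex,
                 extent_bl = extent_bl, bin_size_bl = bin_size_bl,
                 n_obs = n_obs),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> focal %s, %d x %d bins of %.2f BL, %d observations\n",
              x$focal_sex, nrow(x$grid), ncol(x$grid), x$bin_size_bl, x$n_obs))
  invisible(x)
}

#' Plot a density map
#'
#' @param map A [density_map()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_density_map <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_density_map() requires the ggplot2 package.")
  }
  mids <- head(map$breaks, -1) + map$bin_size_bl / 2
  df <- expand.grid(x_bl = mids, y_bl = mids)
  df$density <- as.vector(t(map$grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_bl, y = .data$y_bl,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "partner x (BL)", y = "partner y (BL)",
                  title = paste0("Partner density around focal ",
                                 map$focal_sex, " (heading up)"))
}

#' Both-trapped counts over time
#'
#' For each requested time since trap entry, counts the events whose
#' both-trapped status at that time is observable (the denominator) and the
#' events in which neither individual had escaped by then (the numerator).
#' An event with a censored (`NA`) escape and a recording shorter than `t`
#' is unobservable at `t` and drops out of the denominator; an observed
#' escape before `t` settles the status regardless of recording length.
#'
#' @param events List of trapped [pair_event()] objects.
#' @param times_min Times since entry, in minutes.
#' @return A tibble with columns `time_min`, `both_trapped`, `observed`.
#' @export
trapped_counts <- function(events, times_min = c(10, 20, 30)) {
  if (inherits(events, "pair_event")) events <- list(events)
  if (any(vapply(events, function(e) e$condition, "") != "trapped")) {
    abort("trapped_counts() is defined for trapped events only.")
  }
  per_event <- lapply(events, function(ev) {
    if (is.na(ev$entry_frame)) {
      abort(paste0("event ", ev$pair_id, "/", ev$event_id,
                   " has no entry_frame"))
    }
    last <- min(max(ev$female$frames$frame), max(ev$male$frames$frame))
    to_min <- function(f) (f - ev$entry_frame) / ev$fps / 60
    # allow two frames of slack so that resampling round-off cannot push a
    # recording of exactly t minutes below the t-minute mark
    list(span = to_min(last) + 2 / (ev$fps * 60),
         esc = c(to_min(ev$f_escape_frame), to_min(ev$m_escape_frame)))
  })
  rows <- lapply(times_min, function(t) {
    status <- vapply(per_event, function(e) {
      esc_known <- !is.na(e$esc)
      if (any(esc_known & e$esc <= t)) return(0)          # escape observed
      need_span <- any(!esc_known)                         # censored animal(s)
      if (need_span && e$span < t - 1e-9) return(NA_real_) # unobservable
      1                                                    # both still trapped
    }, numeric(1))
    tibble::tibble(time_min = t,
                   both_trapped = sum(status == 1, na.rm = TRUE),
                   observed = sum(!is.na(status)))
  })
  dplyr::bind_rows(rows)
}
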