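#' Rigidly realign a trajectory
#'
#' Applies the unique rotation-then-translation that maps the trajectory's
#' first position onto `target_origin` and its initial heading onto
#' `target_heading`. This is the realignment used by the randomised-pairing
#' null: a swapped male starts exactly where (and facing exactly how) the
#' original male started, so only the inter-individual coupling is broken.
#' Rigid motions preserve every within-trajectory distance.
#'
#' @param individual A [tracked_individual()] with at least one frame; the
#'   initial heading is the first stored non-missing heading, estimated from
#'   displacements if absent.
#' @param target_origin Numeric length-2 `(x_mm, y_mm)`.
#' @param target_heading Target initial heading in radians.
#' @param min_step_mm Passed to [estimate_heading()] if headings are missing.
#' @return The realigned [tracked_individual()].
#' @export
rigid_align <- function(individual, target_origin, target_heading,
                        min_step_mm = 0) {
  stopifnot(inherits(individual, "tracked_individual"),
            length(target_origin) == 2)
  fr <- individual$frames
  if (nrow(fr) < 1) abort("trajectory has no frames.")
  th0 <- fr$heading_rad[!is.na(fr$heading_rad)][1]
  if (is.na(th0) || length(th0) == 0) {
    fr <- estimate_heading(individual, min_step_mm)$frames
    th0 <- fr$heading_rad[1]
  }
  delta <- target_heading - th0
  R <- rotation_matrix(delta)
  p0 <- c(fr$x_mm[1], fr$y_mm[1])
  rel <- cbind(fr$x_mm - p0[1], fr$y_mm - p0[2]) %*% t(R)
  out <- individual
  out$frames <- fr
  out$frames$x_mm <- rel[, 1] + target_origin[1]
  out$frames$y_mm <- rel[, 2] + target_origin[2]
  out$frames$heading_rad <- ifelse(is.na(fr$heading_rad), NA_real_,
                                   wrap_angle(fr$heading_rad + delta))
  out
}

# Per-event arrays used by the fast null loop: common female/male frames,
# headings filled, plus the male's initial state for realignment targets.
event_arrays <- function(ev, min_step_mm = 0) {
  f <- if (anyNA(ev$female$frames$heading_rad)) {
    estimate_heading(ev$female, min_step_mm)
  } else ev$female
  m <- if (anyNA(ev$male$frames$heading_rad)) {
    estimate_heading(ev$male, min_step_mm)
  } else ev$male
  common <- intersect(f$frames$frame, m$frames$frame)
  ff <- f$frames[match(common, f$frames$frame), ]
  mf <- m$frames[match(common, m$frames$frame), ]
  list(fx = ff$x_mm, fy = ff$y_mm, fth = ff$heading_rad,
       mx = mf$x_mm, my = mf$y_mm, mth = mf$heading_rad,
       bl_f = ev$female$body_length_mm, bl_m = ev$male$body_length_mm,
       n = length(common))
}

# Draw a derangement (fixed-point-free permutation) by rejection sampling.
draw_derangement <- function(n) {
  if (n < 2) abort("derangement impossible: need at least 2 events.")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Randomised-pairing null ensemble
#'
#' Builds the null that breaks inter-individual interaction while preserving
#' individual movement: per replicate, males are re-assigned to females of
#' *different* pairs by a derangement, each swapped male trajectory is
#' rigidly realigned to the original male's initial position and heading,
#' the randomised pair is truncated to the shorter trajectory, and
#' distance/heading-difference metrics are computed exactly as for real
#' pairs. Summaries per replicate are the mean distance (all frames and
#' interaction frames only) and mean heading difference; a seeded subsample
#' of pooled per-frame values is retained for distribution-level (KS)
#' comparisons.
#'
#' @param events List of [pair_event()] objects of one condition, all at the
#'   same frame rate (downsample first).
#' @param n_replicates Number of randomised datasets.
#' @param seed Integer seed; same seed and inputs give an identical ensemble.
#' @param condition If the list mixes conditions, restrict to this one.
#' @param pool_cap Maximum per-frame values kept per replicate and metric for
#'   the pooled subsample.
#' @param min_step_mm Passed to heading estimation.
#' @return An object of class `null_ensemble` with elements `replicates`
#'   (tibble of per-replicate summaries), `pooled` (tibble of subsampled
#'   per-frame values), `permutations` (replicate x event matrix), `seed`,
#'   and `event_ids`.
#' @export
randomize_pairs <- function(events, n_replicates = 1000, seed = 1L,
                            condition = NULL, pool_cap = 100,
                            min_step_mm = 0) {
  if (inherits(events, "pair_event")) events <- list(events)
  conds <- vapply(events, function(e) e$condition, "")
  if (!is.null(condition)) {
    events <- events[conds == condition]
    conds <- conds[conds == condition]
  }
  if (length(unique(conds)) > 1) {
    abort("events mix conditions; pass `condition` to scope the null.")
  }
  n <- length(events)
  if (n < 2) abort("derangement impossible: need at least 2 events of the condition.")
  fpss <- vapply(events, function(e) e$fps, numeric(1))
  if (length(unique(fpss)) > 1) {
    abort("events have differing fps; downsample to a common rate first.")
  }
  arrs <- lapply(events, event_arrays, min_step_mm = min_step_mm)

  set.seed(seed)
  perms <- matrix(NA_integer_, nrow = n_replicates, ncol = n)
  reps <- vector("list", n_replicates)
  pooled <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sigma <- draw_derangement(n)
    perms[r, ] <- sigma
    dist_all <- vector("list", n)
    hdiff_all <- vector("list", n)
    inter_all <- vector("list", n)
    for (i in seq_len(n)) {
      a <- arrs[[i]]            # real female (and original male's start)
      b <- arrs[[sigma[i]]]     # donor male
      k <- min(a$n, b$n)
      # realign donor male to original male's initial position and heading
      delta <- a$mth[1] - b$mth[1]
      cs <- cos(delta); sn <- sin(delta)
      dx <- b$mx[seq_len(k)] - b$mx[1]
      dy <- b$my[seq_len(k)] - b$my[1]
      mx <- a$mx[1] + cs * dx - sn * dy
      my <- a$my[1] + sn * dx + cs * dy
      mth <- b$mth[seq_len(k)] + delta
      fx <- a$fx[seq_len(k)]; fy <- a$fy[seq_len(k)]
      d_mm <- sqrt((fx - mx)^2 + (fy - my)^2)
      bl_mean <- (a$bl_f + b$bl_m) / 2
      dist_all[[i]] <- d_mm / bl_mean
      hdiff_all[[i]] <- unsigned_angle_diff(a$fth[seq_len(k)], mth)
      inter_all[[i]] <- d_mm < (a$bl_f + b$bl_m)
    }
    d <- unlist(dist_all); h <- unlist(hdiff_all); it <- unlist(inter_all)
    reps[[r]] <- tibble::tibble(
      replicate = r,
      mean_distance_bl = mean(d),
      mean_heading_diff = mean(h),
      mean_distance_bl_interacting = if (any(it)) mean(d[it]) else NA_real_,
      mean_heading_diff_interacting = if (any(it)) mean(h[it]) else NA_real_,
      n_frames = length(d), n_interacting = sum(it)
    )
    take <- function(v) if (length(v) > pool_cap)
      v[sample.int(length(v), pool_cap)] else v
    pooled[[r]] <- dplyr::bind_rows(
      tibble::tibble(replicate = r, metric = "distance_bl",
                     filter = "all", value = take(d)),
      tibble::tibble(replicate = r, metric = "heading_diff",
                     filter = "all", value = take(h)),
      tibble::tibble(replicate = r, metric = "distance_bl",
                     filter = "interacting", value = take(d[it])),
      tibble::tibble(replicate = r, metric = "heading_diff",
                     filter = "interacting", value = take(h[it]))
    )
  }
  structure(list(replicates = dplyr::bind_rows(reps),
                 pooled = dplyr::bind_rows(pooled),
                 permutations = perms, seed = as.integer(seed),
                 n_replicates = n_replicates,
                 event_ids = vapply(events, function(e)
                   paste(e$pair_id, e$event_id, sep = "/"), "")),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d replicates over %d events (seed %d)\n",
              x$n_replicates, ncol(x$permutations), x$seed))
  cat(sprintf("  null mean distance: %.3f BL (real pairs excluded by derangement)\n",
              mean(x$replicates$mean_distance_bl)))
  invisible(x)
}

#' Compare real pair metrics against the randomised-pairing null
#'
#' Two complementary comparisons: a distribution-level two-sample test (KS or
#' rank-sum) of the real per-frame values against the pooled null subsample,
#' and a permutation-style placement of the real mean within the null
#' distribution of replicate means (`real_quantile`, with a two-sided
#' permutation p-value `p_perm`). The replicate-mean comparison is the
#' calibrated one: under no interaction the real pairing is exchangeable
#' with the randomised pairings, so `real_quantile` is uniform. The pooled
#' KS treats autocorrelated frames as independent and is reported for
#' distribution shape, as when comparing heading-difference distributions.
#'
#' @param real_metrics Tibble of per-frame metrics for the real pairs
#'   (rows of [pair_metrics()] pooled over events).
#' @param ensemble A `null_ensemble` from [randomize_pairs()].
#' @param metric `"distance_bl"` or `"heading_diff"`.
#' @param test `"ks"` or `"rank_sum"` for the pooled comparison.
#' @param interacting_only Restrict both sides to interaction frames.
#' @return A list with `statistic`, `p_value` (pooled test), `method`,
#'   `real_mean`, `null_mean`, `real_quantile`, `p_perm`, `n_real`, `n_null`.
#' @export
compare_real_null <- function(real_metrics, ensemble,
                              metric = c("distance_bl", "heading_diff"),
                              test = c("ks", "rank_sum"),
                              interacting_only = FALSE) {
  metric <- match.arg(metric)
  test <- match.arg(test)
  stopifnot(inherits(ensemble, "null_ensemble"))
  rm <- real_metrics
  if (interacting_only) rm <- rm[rm$interacting, ]
  real_vals <- rm[[metric]]
  real_vals <- real_vals[!is.na(real_vals)]
  if (length(real_vals) == 0) abort("no real metric values to compare.")
  filt <- if (interacting_only) "interacting" else "all"
  null_vals <- ensemble$pooled$value[ensemble$pooled$metric == metric &
                                       ensemble$pooled$filter == filt]
  null_vals <- null_vals[!is.na(null_vals)]
  if (length(null_vals) == 0) abort("no null metric values to compare.")

  pooled_test <- if (test == "ks") {
    ks_two_sample(real_vals, null_vals)
  } else {
    rank_sum(real_vals, null_vals, exact = FALSE)
  }

  col <- paste0("mean_", metric, if (interacting_only) "_interacting" else "")
  null_means <- ensemble$replicates[[col]]
  null_means <- null_means[!is.na(null_means)]
  real_mean <- mean(real_vals)
  R <- length(null_means)
  q <- (sum(null_means < real_mean) + 0.5 * sum(null_means == real_mean)) / R
  p_lo <- (1 + sum(null_means <= real_mean)) / (R + 1)
  p_hi <- (1 + sum(null_means >= real_mean)) / (R + 1)
  list(statistic = pooled_test$statistic, p_value = pooled_test$p_value,
       method = pooled_test$method,
       real_mean = real_mean, null_mean = mean(null_means),
       real_quantile = q, p_perm = min(1, 2 * min(p_lo, p_hi)),
       n_real = length(real_vals), n_null = length(null_vals))
}
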