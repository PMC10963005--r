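#' Default pipeline configuration
#'
#' Returns the fully resolved configuration list for [run_pipeline()],
#' optionally overridden by a user list or YAML file. Unknown keys are
#' rejected. Every seed used anywhere in the pipeline is derived
#' deterministically from `seed`.
#'
#' @param config A named list of overrides, or a path to a YAML file, or
#'   `NULL` for pure defaults.
#' @return The resolved configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(
      n_natural = 27L, n_trapped = 26L,
      natural_fps = 25, trapped_fps = 30,
      duration_s = 1800,
      params = list()           # synth_params() overrides
    ),
    input = list(tracks = NULL, meta = NULL, flip_y = FALSE),
    analysis = list(
      target_fps = 1, n_replicates = 1000, pool_cap = 100,
      times_min = c(10, 20, 30),
      density_extent_bl = 2, density_bin_bl = 0.1
    ),
    posture = list(
      p_cutoff = 0.9, snapshot = NULL, scale = TRUE,
      fossil_bl_f_mm = 6.5, fossil_bl_m_mm = 5.5
    )
  )
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) return(defaults)
  check_keys <- function(user, def, path = "") {
    extra <- setdiff(names(user), names(def))
    if (length(extra) > 0) {
      abort(paste0("unknown config key(s): ",
                   paste0(path, extra, collapse = ", ")))
    }
    for (k in names(user)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]])) && k != "params") {
        check_keys(user[[k]], def[[k]], paste0(path, k, "."))
      }
    }
  }
  check_keys(config, defaults)
  modifyList(defaults, config)
}

#' Run the full tandem-entrapment analysis pipeline
#'
#' Orchestrates simulate (or load) -> downsample -> spatial metrics ->
#' randomised-pairing null -> posture features -> role classifier ->
#' snapshot classification, and collects every headline statistic in a
#' machine-readable summary. Deterministic given the configuration.
#'
#' Stages: (1) obtain natural and trapped [pair_event()]s, either simulated
#' with [simulate_natural_pair()] / [simulate_trapped_pair()] or read from
#' the tidy track tables in `config$input`; (2) downsample to the analysis
#' rate and compute [pair_metrics()]; (3) compare conditions (speed,
#' inter-individual distance) and count both-trapped events over time;
#' (4) build the [randomize_pairs()] null on the trapped events and compare
#' distance and heading-difference distributions; (5) generate skeleton
#' postures of trapped pairs, test the fTip-mHead vs fHead-mTip asymmetry,
#' fit the [fit_role_classifier()], and classify the snapshot posture (a
#' packaged synthetic fossil-pair stand-in by default).
#'
#' @param config A list or YAML path accepted by [pipeline_config()].
#' @return A list: `summary` (headline statistics), `events`, `metrics`,
#'   `ensemble`, `classifier`, `snapshot_scores`, `density_maps`, `config`.
#'   If `config$out_dir` is set, also writes `summary.json`, `metrics.csv`,
#'   `classifier.json`, density CSVs and the resolved `config.yaml` there.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- pipeline_config(config)
  base_seed <- as.integer(cfg$seed)
  t0 <- Sys.time()
  stage <- function(msg) {
    message(sprintf("[tandemtrap +%5.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))
  }

  # --- events -------------------------------------------------------------
  if (!is.null(cfg$input$tracks)) {
    stage("reading events")
    events <- read_pair_events(cfg$input$tracks, cfg$input$meta,
                               flip_y = cfg$input$flip_y)
  } else {
    stage(sprintf("simulating %d natural + %d trapped events",
                  cfg$simulate$n_natural, cfg$simulate$n_trapped))
    mk_params <- function(fps) {
      do.call(synth_params,
              modifyList(list(fps = fps, duration_s = cfg$simulate$duration_s),
                         cfg$simulate$params))
    }
    p_nat <- mk_params(cfg$simulate$natural_fps)
    p_trap <- mk_params(cfg$simulate$trapped_fps)
    nat <- lapply(seq_len(cfg$simulate$n_natural), function(i) {
      simulate_natural_pair(p_nat, seed = base_seed + i,
                            pair_id = sprintf("nat%02d", i), event_id = "e1")
    })
    trap <- lapply(seq_len(cfg$simulate$n_trapped), function(i) {
      simulate_trapped_pair(p_trap, seed = base_seed + 10000L + i,
                            pair_id = sprintf("trap%02d", i), event_id = "e1")
    })
    events <- c(nat, trap)
  }
  conds <- vapply(events, function(e) e$condition, "")
  if (!any(conds == "trapped")) abort("pipeline stage 'events': no trapped events.")

  # --- metrics ------------------------------------------------------------
  stage("downsampling and computing pair metrics")
  ds <- lapply(events, downsample, target_fps = cfg$analysis$target_fps)
  metrics <- dplyr::bind_rows(lapply(ds, function(ev) {
    dplyr::mutate(pair_metrics(ev), pair_id = ev$pair_id,
                  event_id = ev$event_id, condition = ev$condition)
  }))

  # Speeds are measured at the acquisition rate (sex pooled); for trapped
  # events only frames after trap entry count as "on the sticky surface".
  pooled_speed <- function(cond) {
    unlist(lapply(events[conds == cond], function(ev) {
      keep <- function(s) {
        if (cond == "trapped") s <- s[s$frame >= ev$entry_frame, ]
        s$speed_bl_s
      }
      c(keep(speed_bl_s(ev$female, ev$fps)), keep(speed_bl_s(ev$male, ev$fps)))
    }))
  }
  sp_nat <- na.omit(pooled_speed("natural"))
  sp_trap <- na.omit(pooled_speed("trapped"))
  speed_test <- if (length(sp_nat) > 0) {
    rank_sum(sp_nat, sp_trap, exact = FALSE)
  } else NULL

  event_mean_dist <- vapply(ds, function(ev) {
    m <- pair_metrics(ev)
    mean(m$distance_bl[m$interacting])
  }, numeric(1))
  dist_nat <- event_mean_dist[conds == "natural"]
  dist_trap <- event_mean_dist[conds == "trapped"]
  dist_test <- if (length(dist_nat) > 0) {
    rank_sum(dist_nat, dist_trap)
  } else NULL

  counts <- trapped_counts(ds[conds == "trapped"], cfg$analysis$times_min)

  # --- randomised-pairing null --------------------------------------------
  stage(sprintf("building null ensemble (%d replicates)",
                cfg$analysis$n_replicates))
  trapped_ds <- ds[conds == "trapped"]
  ensemble <- randomize_pairs(trapped_ds,
                              n_replicates = cfg$analysis$n_replicates,
                              seed = base_seed + 20000L,
                              pool_cap = cfg$analysis$pool_cap)
  real_trap_metrics <- metrics[metrics$condition == "trapped", ]
  null_dist <- compare_real_null(real_trap_metrics, ensemble, "distance_bl",
                                 test = "ks")
  null_head <- compare_real_null(real_trap_metrics, ensemble, "heading_diff",
                                 test = "ks")

  # --- density maps --------------------------------------------------------
  stage("density maps")
  dens <- list()
  for (cond in intersect(c("natural", "trapped"), unique(conds))) {
    for (sx in c("F", "M")) {
      dens[[paste0(cond, "_", sx)]] <-
        density_map(ds[conds == cond], focal_sex = sx,
                    extent_bl = cfg$analysis$density_extent_bl,
                    bin_size_bl = cfg$analysis$density_bin_bl)
    }
  }

  # --- posture and role classification ------------------------------------
  stage("posture features and role classifier")
  post_params <- do.call(synth_params, cfg$simulate$params)
  trap_post <- lapply(seq_along(trapped_ds), function(i) {
    skeleton_postures(trapped_ds[[i]], post_params,
                      seed = base_seed + 30000L + i)
  })
  tip_head <- dplyr::bind_rows(lapply(seq_along(trapped_ds), function(i) {
    tip_head_distances(trap_post[[i]],
                       trapped_ds[[i]]$female$body_length_mm,
                       trapped_ds[[i]]$male$body_length_mm)
  }))
  tip_test <- paired_t(tip_head$d_fHead_mTip, tip_head$d_fTip_mHead)

  # Training set: in the reference species the female always leads, so
  # female-focal rows are leaders and male-focal rows followers.
  train <- dplyr::bind_rows(lapply(seq_along(trapped_ds), function(i) {
    ev <- trapped_ds[[i]]
    nb <- mean_body_length(ev)
    dplyr::bind_rows(
      relative_head_features(trap_post[[i]], "F", nb, role = "leader",
                             source_id = ev$pair_id),
      relative_head_features(trap_post[[i]], "M", nb, role = "follower",
                             source_id = ev$pair_id)
    )
  }))
  classifier <- fit_role_classifier(train, scale = cfg$posture$scale)

  snapshot_path <- cfg$posture$snapshot
  if (is.null(snapshot_path)) {
    snapshot_path <- system.file("extdata", "fossil_snapshot_synthetic.csv",
                                 package = "tandemtrap")
  }
  snap <- read_posture_table(snapshot_path, p_cutoff = cfg$posture$p_cutoff)
  fossil_bl <- (cfg$posture$fossil_bl_f_mm + cfg$posture$fossil_bl_m_mm) / 2
  snap_features <- dplyr::bind_rows(
    relative_head_features(snap, "F", fossil_bl, source_id = "snapshot"),
    relative_head_features(snap, "M", fossil_bl, source_id = "snapshot")
  )
  snap_scores <- classify_snapshot(classifier, snap_features)
  fem <- snap_scores[snap_scores$focal_sex == "F", ]
  mal <- snap_scores[snap_scores$focal_sex == "M", ]

  summary <- list(
    schema_version = "1.0",
    n_events = list(natural = sum(conds == "natural"),
                    trapped = sum(conds == "trapped")),
    speed_bl_s = list(
      natural_mean = if (length(sp_nat)) mean(sp_nat) else NA,
      natural_sd = if (length(sp_nat)) sd(sp_nat) else NA,
      trapped_mean = mean(sp_trap), trapped_sd = sd(sp_trap),
      rank_sum_p = if (!is.null(speed_test)) speed_test$p_value else NA),
    distance_bl = list(
      natural_event_means = unname(dist_nat),
      trapped_event_means = unname(dist_trap),
      rank_sum_W = if (!is.null(dist_test)) dist_test$statistic else NA,
      rank_sum_p = if (!is.null(dist_test)) dist_test$p_value else NA),
    trapped_counts = counts,
    null_comparison = list(
      distance = null_dist[c("statistic", "p_value", "real_mean",
                             "null_mean", "real_quantile", "p_perm")],
      heading_diff = null_head[c("statistic", "p_value", "real_mean",
                                 "null_mean", "real_quantile", "p_perm")]),
    posture = list(
      tip_head_t = tip_test$statistic, tip_head_p = tip_test$p_value,
      n_posture_frames = nrow(tip_head),
      pca_var_fractions = unname(classifier$pca_var_fractions),
      pca_loadings = classifier$pca_loadings,
      fossil_female_p_follower = fem$p_follower,
      fossil_male_p_leader = mal$p_leader)
  )

  if (!is.null(cfg$out_dir)) {
    stage(paste0("writing outputs to ", cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(coefficients = as.list(classifier$coefficients),
           center = as.list(classifier$center),
           scale = as.list(classifier$scale),
           pca_loadings = classifier$pca_loadings,
           pca_var_fractions = classifier$pca_var_fractions,
           n = classifier$n, class_balance = classifier$class_balance),
      file.path(cfg$out_dir, "classifier.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(dens)) {
      utils::write.table(dens[[nm]]$grid,
                         file.path(cfg$out_dir, paste0("density_", nm, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
    cfg_out <- cfg
    cfg_out$out_dir <- NULL
    yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "config.yaml"))
  }
  stage("done")
  invisible(list(summary = summary, events = events, metrics = metrics,
                 ensemble = ensemble, classifier = classifier,
                 snapshot_scores = snap_scores, density_maps = dens,
                 config = cfg))
}
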