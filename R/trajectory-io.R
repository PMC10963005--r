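#' Read pair events from tidy trajectory and metadata tables
#'
#' Reads a long-format tracks table (one row per animal per frame) and an
#' event metadata table, and assembles validated [pair_event()] objects.
#'
#' @param tracks_path CSV with columns `pair_id`, `event_id`, `sex` (`F`/`M`),
#'   `frame`, `x_mm`, `y_mm` and optionally `heading_rad`.
#' @param meta_path CSV with one row per event: `pair_id`, `event_id`,
#'   `condition` (`natural`/`trapped`), `fps`, `body_length_f_mm`,
#'   `body_length_m_mm`, and (trapped events) `entry_frame`,
#'   `f_escape_frame`, `m_escape_frame` (empty = censored).
#' @param flip_y If `TRUE`, negate y coordinates on input. Use for tables
#'   exported from image-coordinate systems (y increasing downward); the
#'   package convention is y-up.
#'
#' @return A list of [pair_event()] objects, ordered as in the metadata table.
#' @export
read_pair_events <- function(tracks_path, meta_path, flip_y = FALSE) {
  tracks <- readr::read_csv(tracks_path, show_col_types = FALSE,
                            progress = FALSE)
  meta <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE)
  required_tracks <- c("pair_id", "event_id", "sex", "frame", "x_mm", "y_mm")
  missing_cols <- setdiff(required_tracks, names(tracks))
  if (length(missing_cols) > 0) {
    abort(paste0("tracks table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  required_meta <- c("pair_id", "event_id", "condition", "fps",
                     "body_length_f_mm", "body_length_m_mm")
  missing_cols <- setdiff(required_meta, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (flip_y) tracks$y_mm <- -tracks$y_mm
  if (!"heading_rad" %in% names(tracks)) tracks$heading_rad <- NA_real_

  track_keys <- unique(paste(tracks$pair_id, tracks$event_id, sep = "\r"))
  meta_keys <- paste(meta$pair_id, meta$event_id, sep = "\r")
  orphans <- setdiff(track_keys, meta_keys)
  if (length(orphans) > 0) {
    abort(paste0("no metadata row for event(s): ",
                 paste(gsub("\r", "/", orphans), collapse = ", ")))
  }

  opt_int <- function(row, col) {
    if (!col %in% names(row) || is.na(row[[col]])) NA_integer_
    else as.integer(row[[col]])
  }

  events <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    row <- meta[i, ]
    sub <- tracks[tracks$pair_id == row$pair_id &
                    tracks$event_id == row$event_id, ]
    if (nrow(sub) == 0) {
      abort(paste0("no track rows for event ", row$pair_id, "/", row$event_id))
    }
    make_ind <- function(sex_code, bl, label) {
      s <- sub[sub$sex == sex_code, ]
      if (nrow(s) == 0) {
        abort(paste0(label, " track missing for event ",
                     row$pair_id, "/", row$event_id))
      }
      s <- s[order(s$frame), ]
      tracked_individual(
        individual_id = paste(row$pair_id, row$event_id, sex_code, sep = "_"),
        sex = sex_code, body_length_mm = bl,
        frames = s[, c("frame", "x_mm", "y_mm", "heading_rad")]
      )
    }
    events[[i]] <- pair_event(
      pair_id = row$pair_id, event_id = row$event_id,
      condition = row$condition, fps = row$fps,
      female = make_ind("F", row$body_length_f_mm, "female"),
      male = make_ind("M", row$body_length_m_mm, "male"),
      entry_frame = opt_int(row, "entry_frame"),
      f_escape_frame = opt_int(row, "f_escape_frame"),
      m_escape_frame = opt_int(row, "m_escape_frame")
    )
  }
  events
}

#' Write pair events to tidy trajectory and metadata tables
#'
#' Inverse of [read_pair_events()]; the round trip reproduces identical
#' records.
#'
#' @param events List of [pair_event()] objects.
#' @param tracks_path,meta_path Output CSV paths.
#' @return Invisibly, the list of written paths.
#' @export
write_pair_events <- function(events, tracks_path, meta_path) {
  stopifnot(is.list(events), length(events) > 0)
  track_rows <- lapply(events, function(ev) {
    dplyr::bind_rows(lapply(list(ev$female, ev$male), function(ind) {
      tibble::tibble(pair_id = ev$pair_id, event_id = ev$event_id,
                     sex = ind$sex, frame = ind$frames$frame,
                     x_mm = ind$frames$x_mm, y_mm = ind$frames$y_mm,
                     heading_rad = ind$frames$heading_rad)
    }))
  })
  meta_rows <- lapply(events, function(ev) {
    tibble::tibble(pair_id = ev$pair_id, event_id = ev$event_id,
                   condition = ev$condition, fps = ev$fps,
                   body_length_f_mm = ev$female$body_length_mm,
                   body_length_m_mm = ev$male$body_length_mm,
                   entry_frame = ev$entry_frame,
                   f_escape_frame = ev$f_escape_frame,
                   m_escape_frame = ev$m_escape_frame)
  })
  readr::write_csv(dplyr::bind_rows(track_rows), tracks_path, progress = FALSE)
  readr::write_csv(dplyr::bind_rows(meta_rows), meta_path, progress = FALSE)
  invisible(list(tracks = tracks_path, meta = meta_path))
}

#' Read a posture table with a likelihood cutoff
#'
#' Reads body-part coordinates for the six tracked points of a tandem pair
#' (`fHead`, `fPro`, `fTip`, `mHead`, `mPro`, `mTip`) and masks low-confidence
#' points. Two dialects are accepted: the pose-estimation export dialect with
#' three header rows (`scorer` / `bodyparts` / `coords`, then one
#' `x,y,likelihood` triple per body part), and tidy long form with columns
#' `frame`, `bodypart`, `x_mm`, `y_mm`, `likelihood`.
#'
#' Points whose likelihood falls below `p_cutoff` have their coordinates set
#' to `NA` (the likelihood itself is retained), so low-confidence detections
#' can never leak into downstream geometry.
#'
#' @param path CSV path in either dialect.
#' @param p_cutoff Likelihood cutoff in `[0, 1]`; default 0.9.
#' @param flip_y If `TRUE`, negate y on input (image-origin data).
#'
#' @return A tibble with columns `frame`, `bodypart`, `x_mm`, `y_mm`,
#'   `likelihood`, ordered by frame then body part.
#' @export
read_posture_table <- function(path, p_cutoff = 0.9, flip_y = FALSE) {
  if (!is.numeric(p_cutoff) || length(p_cutoff) != 1 ||
      is.na(p_cutoff) || p_cutoff < 0 || p_cutoff > 1) {
    abort("`p_cutoff` must be a single number in [0, 1].")
  }
  first <- strsplit(readLines(path, n = 1L), ",")[[1]]
  long <- if (identical(first[1], "scorer")) {
    read_posture_wide(path)
  } else if (all(c("frame", "bodypart") %in% first)) {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    required <- c("frame", "bodypart", "x_mm", "y_mm", "likelihood")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("tidy posture table is missing columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    tibble::as_tibble(df[, required])
  } else {
    abort(paste0("unrecognised posture dialect: expected a 'scorer' header ",
                 "(pose-estimation export) or tidy columns frame/bodypart/",
                 "x_mm/y_mm/likelihood."))
  }
  unknown <- setdiff(unique(long$bodypart), BODYPART_LABELS)
  if (length(unknown) > 0) {
    abort(paste0("unknown body part(s): ", paste(unknown, collapse = ", "),
                 "; expected: ", paste(BODYPART_LABELS, collapse = ", ")))
  }
  if (flip_y) long$y_mm <- -long$y_mm
  low <- !is.na(long$likelihood) & long$likelihood < p_cutoff
  long$x_mm[low] <- NA_real_
  long$y_mm[low] <- NA_real_
  long[order(long$frame, match(long$bodypart, BODYPART_LABELS)), ]
}

# Parse the three-header-row pose-estimation export dialect into long form.
read_posture_wide <- function(path) {
  hdr <- readLines(path, n = 3L)
  rows <- lapply(hdr, function(l) strsplit(l, ",")[[1]])
  if (length(rows) < 3 || !identical(rows[[2]][1], "bodyparts") ||
      !identical(rows[[3]][1], "coords")) {
    abort(paste0("malformed pose-estimation header: expected rows ",
                 "'scorer', 'bodyparts', 'coords'."))
  }
  parts <- rows[[2]][-1]
  coords <- rows[[3]][-1]
  if (length(parts) != length(coords) ||
      !all(coords %in% c("x", "y", "likelihood"))) {
    abort("malformed pose-estimation header: coords row must be x/y/likelihood triples.")
  }
  body <- readr::read_csv(path, skip = 3, col_names = FALSE,
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(body) != length(parts) + 1) {
    abort("pose-estimation table width does not match its header.")
  }
  frames <- as.integer(body[[1]])
  pieces <- lapply(unique(parts), function(bp) {
    idx <- which(parts == bp) + 1L  # +1 for the frame-index column
    cs <- coords[parts == bp]
    tibble::tibble(frame = frames, bodypart = bp,
                   x_mm = as.numeric(body[[idx[cs == "x"]]]),
                   y_mm = as.numeric(body[[idx[cs == "y"]]]),
                   likelihood = as.numeric(body[[idx[cs == "likelihood"]]]))
  })
  dplyr::bind_rows(pieces)
}

#' Downsample a pair event to a lower frame rate
#'
#' Keeps frames whose offset from the event's first frame is a multiple of
#' `fps / target_fps` (which must be an integer), mirroring the usual practice
#' of analysing trajectories at 1 FPS regardless of acquisition rate. Kept
#' frames are renumbered consecutively so that frame indices stay consistent
#' with the new rate; entry and escape frames are mapped to the nearest kept
#' frame at or after the original.
#'
#' @param event A [pair_event()].
#' @param target_fps Target frame rate; `fps` must be an integer multiple.
#' @return The downsampled [pair_event()] with `fps = target_fps`.
#' @export
downsample <- function(event, target_fps = 1) {
  stopifnot(inherits(event, "pair_event"))
  ratio <- event$fps / target_fps
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort(paste0("fps (", event$fps, ") is not an integer multiple of ",
                 "target_fps (", target_fps, "); resampling to non-divisor ",
                 "rates is out of scope."))
  }
  k <- as.integer(round(ratio))
  first <- min(event$female$frames$frame, event$male$frames$frame)
  thin <- function(ind) {
    keep <- (ind$frames$frame - first) %% k == 0
    ind$frames <- ind$frames[keep, ]
    ind$frames$frame <- as.integer((ind$frames$frame - first) / k)
    ind
  }
  snap_up <- function(f) {
    if (is.na(f)) return(NA_integer_)
    as.integer(ceiling((f - first) / k))
  }
  ev <- event
  ev$female <- thin(event$female)
  ev$male <- thin(event$male)
  ev$fps <- target_fps
  ev$entry_frame <- snap_up(event$entry_frame)
  ev$f_escape_frame <- snap_up(event$f_escape_frame)
  ev$m_escape_frame <- snap_up(event$m_escape_frame)
  ev
}
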