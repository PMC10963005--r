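#' Construct a tracked individual
#'
#' A `tracked_individual` holds one animal's per-frame centroid series (in mm)
#' with an optional heading, together with its body length. Body length is the
#' head-to-abdomen-tip length used throughout to normalise distances and
#' speeds into body-length (BL) units.
#'
#' @param individual_id Character scalar identifying the animal.
#' @param sex `"F"` or `"M"`.
#' @param body_length_mm Positive body length in millimetres.
#' @param frames A data frame with columns `frame` (integer, strictly
#'   increasing, 0-based), `x_mm`, `y_mm`, and optionally `heading_rad`
#'   (radians CCW from +x in `[0, 2*pi)`, `NA` allowed). Coordinates use a
#'   y-up axis convention.
#'
#' @return An object of class `tracked_individual`.
#' @export
tracked_individual <- function(individual_id, sex, body_length_mm, frames) {
  sex <- match.arg(sex, c("F", "M"))
  if (!is.numeric(body_length_mm) || length(body_length_mm) != 1 ||
      is.na(body_length_mm) || body_length_mm <= 0) {
    abort("`body_length_mm` must be a single positive number.")
  }
  frames <- tibble::as_tibble(frames)
  required <- c("frame", "x_mm", "y_mm")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols) > 0) {
    abort(paste0("`frames` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"heading_rad" %in% names(frames)) frames$heading_rad <- NA_real_
  frames <- frames[, c("frame", "x_mm", "y_mm", "heading_rad")]
  if (anyDuplicated(frames$frame)) {
    abort(paste0("duplicated frame index for individual '", individual_id, "'"))
  }
  if (is.unsorted(frames$frame, strictly = TRUE)) {
    abort(paste0("frame indices must be strictly increasing for individual '",
                 individual_id, "'"))
  }
  ok <- is.na(frames$heading_rad) |
    (frames$heading_rad >= 0 & frames$heading_rad < 2 * pi)
  if (!all(ok)) {
    abort("`heading_rad` must lie in [0, 2*pi) or be NA.")
  }
  structure(
    list(individual_id = as.character(individual_id), sex = sex,
         body_length_mm = as.numeric(body_length_mm), frames = frames),
    class = "tracked_individual"
  )
}

#' Construct a pair event
#'
#' A `pair_event` bundles the female and male trajectories of one recording
#' (natural tandem run) or one trap-entry event (sticky-surface condition),
#' with its acquisition metadata. Frame indices are 0-based; escape frames of
#' `NA` encode right-censoring (the animal was still trapped when the
#' recording ended).
#'
#' @param pair_id,event_id Character identifiers; a pair can contribute
#'   several trap-entry events.
#' @param condition `"natural"` or `"trapped"`.
#' @param fps Recording frame rate (frames per second), positive.
#' @param female,male `tracked_individual` objects with matching sexes.
#' @param entry_frame Frame at which the leader entered the sticky surface
#'   (trapped condition only, `NA` otherwise).
#' @param f_escape_frame,m_escape_frame Frame at which the female / male
#'   escaped the sticky surface; `NA` = censored.
#'
#' @return An object of class `pair_event`.
#' @export
pair_event <- function(pair_id, event_id, condition, fps, female, male,
                       entry_frame = NA_integer_,
                       f_escape_frame = NA_integer_,
                       m_escape_frame = NA_integer_) {
  condition <- match.arg(condition, c("natural", "trapped"))
  if (!inherits(female, "tracked_individual") ||
      !inherits(male, "tracked_individual")) {
    abort("`female` and `male` must be tracked_individual objects.")
  }
  if (female$sex != "F") abort("`female` must have sex 'F'.")
  if (male$sex != "M") abort("`male` must have sex 'M'.")
  if (!is.numeric(fps) || length(fps) != 1 || is.na(fps) || fps <= 0) {
    abort("`fps` must be a single positive number.")
  }
  if (condition == "natural" &&
      (!is.na(entry_frame) || !is.na(f_escape_frame) || !is.na(m_escape_frame))) {
    abort("natural events must not carry entry/escape frames.")
  }
  for (esc in list(f_escape_frame, m_escape_frame)) {
    if (!is.na(esc) && !is.na(entry_frame) && esc < entry_frame) {
      abort("escape frame precedes entry frame.")
    }
  }
  structure(
    list(pair_id = as.character(pair_id), event_id = as.character(event_id),
         condition = condition, fps = as.numeric(fps),
         female = female, male = male,
         entry_frame = as.integer(entry_frame),
         f_escape_frame = as.integer(f_escape_frame),
         m_escape_frame = as.integer(m_escape_frame)),
    class = "pair_event"
  )
}

#' @export
print.tracked_individual <- function(x, ...) {
  cat(sprintf("<tracked_individual> %s (%s), BL %.2f mm, %d frames\n",
              x$individual_id, x$sex, x$body_length_mm, nrow(x$frames)))
  invisible(x)
}

#' @export
print.pair_event <- function(x, ...) {
  cat(sprintf("<pair_event> pair %s event %s [%s], %g fps, %d/%d frames (F/M)\n",
              x$pair_id, x$event_id, x$condition, x$fps,
              nrow(x$female$frames), nrow(x$male$frames)))
  if (!is.na(x$entry_frame)) {
    cat(sprintf("  entry at frame %d; escapes F=%s M=%s\n", x$entry_frame,
                ifelse(is.na(x$f_escape_frame), "censored", x$f_escape_frame),
                ifelse(is.na(x$m_escape_frame), "censored", x$m_escape_frame)))
  }
  invisible(x)
}

# Mean body length of the pair, the package-wide BL normalisation unit.
mean_body_length <- function(event) {
  (event$female$body_length_mm + event$male$body_length_mm) / 2
}
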