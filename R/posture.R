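# Reshape a long posture table to one row per frame with x/y per body part.
posture_wide <- function(postures) {
  stopifnot(all(c("frame", "bodypart", "x_mm", "y_mm") %in% names(postures)))
  tidyr::pivot_wider(postures[, c("frame", "bodypart", "x_mm", "y_mm")],
                     names_from = "bodypart",
                     values_from = c("x_mm", "y_mm"))
}

point_dist <- function(w, a, b) {
  sqrt((w[[paste0("x_mm_", a)]] - w[[paste0("x_mm_", b)]])^2 +
         (w[[paste0("y_mm_", a)]] - w[[paste0("y_mm_", b)]])^2)
}

#' Tip-to-head distance asymmetry of a tandem pair
#'
#' Per frame, the two cross distances that diagnose who follows whom: female
#' abdomen tip to male head (`d_fTip_mHead`) and female head to male abdomen
#' tip (`d_fHead_mTip`), in body lengths (normalised by the mean of the two
#' body lengths). In a female-led tandem the follower male keeps his head at
#' the female's abdomen tip, so `d_fTip_mHead` is the short one. Frames
#' missing any of the four points are dropped.
#'
#' @param postures Long posture tibble (see [read_posture_table()]).
#' @param f_bl,m_bl Female and male body lengths in mm.
#' @return A tibble with columns `frame`, `d_fTip_mHead`, `d_fHead_mTip`.
#' @export
tip_head_distances <- function(postures, f_bl, m_bl) {
  w <- posture_wide(postures)
  need <- c("fTip", "mHead", "fHead", "mTip")
  cols <- c(paste0("x_mm_", need), paste0("y_mm_", need))
  missing_cols <- setdiff(cols, names(w))
  if (length(missing_cols) > 0) {
    abort(paste0("posture table lacks body part columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bl_mean <- (f_bl + m_bl) / 2
  out <- tibble::tibble(
    frame = w$frame,
    d_fTip_mHead = point_dist(w, "fTip", "mHead") / bl_mean,
    d_fHead_mTip = point_dist(w, "fHead", "mTip") / bl_mean
  )
  out <- out[!is.na(out$d_fTip_mHead) & !is.na(out$d_fHead_mTip), ]
  if (nrow(out) == 0) abort("no complete frame with fTip/mHead/fHead/mTip.")
  out
}

#' Relative-head-position features
#'
#' For each frame, the distance from the focal animal's head to the three
#' body parts of its partner (head, pronotum, abdomen tip), divided by
#' `norm_bl`. These three normalised distances are the classifier's feature
#' vector: a follower's head sits at its partner's abdomen tip (small
#' head-abdomen distance), a leader's head is far from all partner parts.
#' Frames missing any required point are skipped with a warning.
#'
#' @param postures Long posture tibble.
#' @param focal_sex `"F"` or `"M"`.
#' @param norm_bl Normalising length in mm, typically the pair's mean body
#'   length.
#' @param role Role label to attach: `"leader"`, `"follower"` or `"unknown"`.
#' @param source_id Identifier recorded with each row.
#' @return A tibble with columns `source_id`, `frame`, `focal_sex`, `role`,
#'   `d_head_head`, `d_head_pronotum`, `d_head_abdomen`.
#' @export
relative_head_features <- function(postures, focal_sex = c("F", "M"),
                                   norm_bl, role = "unknown",
                                   source_id = "posture") {
  focal_sex <- match.arg(focal_sex)
  role <- match.arg(role, c("leader", "follower", "unknown"))
  if (!is.numeric(norm_bl) || norm_bl <= 0) abort("`norm_bl` must be positive.")
  w <- posture_wide(postures)
  me <- tolower(focal_sex)
  other <- setdiff(c("f", "m"), me)
  need <- c(paste0(me, "Head"), paste0(other, c("Head", "Pro", "Tip")))
  cols <- c(paste0("x_mm_", need), paste0("y_mm_", need))
  missing_cols <- setdiff(cols, names(w))
  if (length(missing_cols) > 0) {
    abort(paste0("posture table lacks body part columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    source_id = source_id, frame = w$frame, focal_sex = focal_sex,
    role = role,
    d_head_head = point_dist(w, paste0(me, "Head"), paste0(other, "Head")) / norm_bl,
    d_head_pronotum = point_dist(w, paste0(me, "Head"), paste0(other, "Pro")) / norm_bl,
    d_head_abdomen = point_dist(w, paste0(me, "Head"), paste0(other, "Tip")) / norm_bl
  )
  keep <- !is.na(out$d_head_head) & !is.na(out$d_head_pronotum) &
    !is.na(out$d_head_abdomen)
  if (any(!keep)) {
    warn(sprintf("%d frame(s) skipped: missing body points.", sum(!keep)))
  }
  out[keep, ]
}

feature_cols <- c("d_head_head", "d_head_pronotum", "d_head_abdomen")

#' Fit the leader/follower role classifier
#'
#' Centres and scales the three relative-head-position distances, fits an
#' unregularised logistic regression of role on them (log-odds of *leader*),
#' and fits a PCA on the same standardised matrix for visualisation. The fit
#' is deterministic given the data. Perfect separation is tolerated with a
#' warning (coefficients stop at the glm convergence tolerance).
#'
#' @param features Tibble from [relative_head_features()] with `role` set to
#'   `"leader"` or `"follower"`; at least 10 rows of each.
#' @param scale If `TRUE` (default) features are standardised to unit
#'   variance (correlation-style PCA); if `FALSE` they are only centred.
#' @return An object of class `role_classifier`: coefficients, normalisation
#'   constants, PCA loadings and explained-variance fractions, and a training
#'   summary.
#' @export
fit_role_classifier <- function(features, scale = TRUE) {
  stopifnot(all(c("role", feature_cols) %in% names(features)))
  roles <- features$role
  if (!all(roles %in% c("leader", "follower"))) {
    abort("training features must be labelled 'leader' or 'follower'.")
  }
  tab <- table(factor(roles, c("leader", "follower")))
  if (any(tab == 0)) abort("both classes must be present to fit the classifier.")
  if (any(tab < 10)) abort("need at least 10 frames per class.")
  X <- as.matrix(features[, feature_cols])
  center <- colMeans(X)
  scl <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
  if (any(scl == 0)) abort("a feature has zero variance; cannot standardise.")
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  df <- data.frame(Z, is_leader = as.integer(roles == "leader"))
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    glm(is_leader ~ d_head_head + d_head_pronotum + d_head_abdomen,
        data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep_warning) {
    warn("classes are (quasi-)separated; logistic coefficients are capped by the glm convergence tolerance.")
  }
  pca <- prcomp(Z, center = FALSE, scale. = FALSE)
  evf <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(coefficients = coef(fit), center = center, scale = scl,
                 scaled = scale,
                 pca_loadings = pca$rotation,
                 pca_var_fractions = evf,
                 pca_scores = pca$x,
                 n = nrow(X), class_balance = as.vector(tab["leader"]) / nrow(X),
                 separated = sep_warning),
            class = "role_classifier")
}

#' @export
print.role_classifier <- function(x, ...) {
  cat(sprintf("<role_classifier> logistic fit on %d frames (%.0f%% leader)\n",
              x$n, 100 * x$class_balance))
  cat("  log-odds(leader) coefficients (standardised features):\n")
  print(round(x$coefficients, 3))
  cat(sprintf("  PCA explained variance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$pca_var_fractions),
                    collapse = ", ")))
  invisible(x)
}

#' Classify snapshot postures into leader/follower roles
#'
#' Scores each feature row independently — as for a fossil pair, where each
#' individual is scored as focal once and the two probabilities need not be
#' complementary.
#'
#' @param model A fitted [fit_role_classifier()] object.
#' @param features Tibble of [relative_head_features()] rows (role may be
#'   `"unknown"`), normalised with the same convention as the training data.
#' @return A tibble with `source_id`, `frame`, `focal_sex`, `p_leader`,
#'   `p_follower`, and the PCA scores of each row (`PC1`..`PC3`) for
#'   plotting against the training cloud.
#' @export
classify_snapshot <- function(model, features) {
  if (!inherits(model, "role_classifier")) {
    abort("`model` must be a fitted role_classifier.")
  }
  X <- as.matrix(features[, feature_cols])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  eta <- model$coefficients[1] + Z %*% model$coefficients[-1]
  p <- plogis(as.vector(eta))
  scores <- Z %*% model$pca_loadings
  tibble::tibble(source_id = features$source_id, frame = features$frame,
                 focal_sex = features$focal_sex,
                 p_leader = p, p_follower = 1 - p,
                 PC1 = scores[, 1], PC2 = scores[, 2], PC3 = scores[, 3])
}
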