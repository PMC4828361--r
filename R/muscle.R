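# transform a muscle path's attachment points to global coordinates at frame f
muscle_points_global <- function(path, poses, f) {
  n <- nrow(path$points)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ps <- poses[[path$segments[i]]]
    if (is.null(ps)) stop("no pose series for segment '", path$segments[i], "'")
    if (!ps$valid[f]) return(NULL)
    out[i, ] <- as.numeric(ps$R[, , f] %*% path$points[i, ]) + ps$t[f, ]
  }
  out
}

#' Muscle path length at one frame
#'
#' Transforms each attachment point to global coordinates through its
#' segment's pose and sums consecutive point-to-point Euclidean distances
#' along the polyline.
#'
#' @param path a [muscle_path].
#' @param poses named list of `pose_series` (from [fit_poses()]).
#' @param frame 1-based frame index.
#' @return length in mm, or `NA` when any needed segment pose is invalid at
#'   that frame.
#' @export
muscle_length <- function(path, poses, frame) {
  pts <- muscle_points_global(path, poses, frame)
  if (is.null(pts)) return(NA_real_)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Muscle rest length at a neutral posture
#'
#' Evaluates [muscle_length()] at a single-frame pose set representing the
#' neutral anatomical standing posture; this is the denominator for
#' normalised lengthening.
#'
#' @param path a [muscle_path].
#' @param neutral_poses named list of `pose_series` with (at least) one
#'   valid frame.
#' @param frame frame of `neutral_poses` to use.
#' @return rest length in mm.
#' @export
compute_rest_length <- function(path, neutral_poses, frame = 1) {
  len <- muscle_length(path, neutral_poses, frame)
  if (!is.finite(len) || len <= 0)
    stop("cannot compute rest length of '", path$name,
         "': invalid neutral pose")
  len
}

#' Neutral-posture poses of a model
#'
#' The identity pose of every segment (the neutral standing posture by the
#' model's construction): rotation identity, origin at the segment's
#' neutral joint-centre position.
#'
#' @param model a `skeleton_model`.
#' @return named list of single-frame `pose_series`.
#' @export
neutral_poses <- function(model) {
  org <- neutral_origins(model)
  out <- list()
  for (nm in model$order) {
    out[[nm]] <- structure(
      list(segment = nm, R = array(diag(3), dim = c(3, 3, 1)),
           t = matrix(org[[nm]], 1, 3), residual = 0, valid = TRUE,
           frame_rate = 1, n_frames = 1L),
      class = "pose_series")
  }
  out
}

# neutral global joint-centre positions, composed down the tree
neutral_origins <- function(model) {
  org <- list()
  for (nm in model$order) {
    s <- model$segments[[nm]]
    org[[nm]] <- if (is.na(s$parent)) s$joint_offset else
      org[[s$parent]] + s$joint_offset
  }
  org
}

#' Normalise a length series to percent of rest length
#'
#' @param length_series numeric lengths (mm).
#' @param rest_length rest length (mm), > 0.
#' @return numeric series, 100 * length / rest_length (percent).
#' @export
normalized_lengthening <- function(length_series, rest_length) {
  if (!is.finite(rest_length) || rest_length <= 0)
    stop("rest_length must be a positive number")
  100 * length_series / rest_length
}

#' Lengthening speed of a muscle
#'
#' Central-difference time derivative of the length series, converted from
#' mm/s to m/s; positive while the muscle lengthens.
#'
#' @param length_series numeric lengths (mm).
#' @param frame_rate Hz.
#' @return list with `speed` (m/s per frame) and `max` (largest positive
#'   lengthening speed; 0 if the muscle never lengthens).
#' @export
lengthening_speed <- function(length_series, frame_rate) {
  n <- length(length_series)
  if (sum(is.finite(length_series)) < 3)
    stop("lengthening speed needs at least 3 valid frames")
  dt <- 1 / frame_rate
  sp <- numeric(n)
  sp[1] <- (length_series[2] - length_series[1]) / dt
  sp[n] <- (length_series[n] - length_series[n - 1]) / dt
  sp[2:(n - 1)] <- (length_series[3:n] - length_series[1:(n - 2)]) / (2 * dt)
  sp <- sp / 1000                      # mm/s -> m/s
  pos <- sp[is.finite(sp) & sp > 0]
  list(speed = sp, max = if (length(pos) > 0) max(pos) else 0)
}

#' Classify the muscular work pattern frame by frame
#'
#' Kinematic proxy for the eccentric / concentric / isometric distinction:
#' `lengthening` when dL/dt exceeds `+dead_band`, `shortening` below
#' `-dead_band`, `isometric` inside the band. (Without activation data a
#' lengthening muscle is only presumed to be loaded eccentrically.)
#'
#' @param length_series numeric lengths (mm).
#' @param frame_rate Hz.
#' @param dead_band m/s; half-width of the isometric band.
#' @return character vector per frame: `"lengthening"`, `"shortening"` or
#'   `"isometric"`.
#' @export
classify_work_pattern <- function(length_series, frame_rate,
                                  dead_band = 0.005) {
  sp <- lengthening_speed(length_series, frame_rate)$speed
  out <- rep("isometric", length(sp))
  out[sp > dead_band] <- "lengthening"
  out[sp < -dead_band] <- "shortening"
  out
}

#' Full per-muscle length series
#'
#' Evaluates a muscle's path length on every frame, normalises to rest
#' length, and derives the lengthening-speed and work-pattern series.
#'
#' @param path a [muscle_path].
#' @param poses named list of `pose_series` for the trial.
#' @param rest_length rest length (mm); computed from `model` at the neutral
#'   posture when omitted.
#' @param model `skeleton_model`, needed only when `rest_length` is missing.
#' @param dead_band isometric dead band, m/s.
#' @return object of class `muscle_series`: `muscle`, `length_mm`,
#'   `pct_rest`, `speed_ms`, `pattern`, `rest_length_mm`, `frame_rate`.
#' @export
muscle_series <- function(path, poses, rest_length = NULL, model = NULL,
                          dead_band = 0.005) {
  if (is.null(rest_length)) {
    if (is.null(model)) stop("supply rest_length or a model to derive it from")
    rest_length <- compute_rest_length(path, neutral_poses(model))
  }
  fr <- poses[[path$segments[1]]]$frame_rate
  nf <- poses[[path$segments[1]]]$n_frames
  len <- vapply(seq_len(nf), function(f) muscle_length(path, poses, f),
                numeric(1))
  sp <- lengthening_speed(len, fr)
  structure(list(muscle = path$name, length_mm = len,
                 pct_rest = normalized_lengthening(len, rest_length),
                 speed_ms = sp$speed, max_speed_ms = sp$max,
                 pattern = classify_work_pattern(len, fr, dead_band),
                 rest_length_mm = rest_length, frame_rate = fr),
            class = "muscle_series")
}

#' @export
print.muscle_series <- function(x, ...) {
  cat(sprintf(
    "muscle_series '%s': rest %.1f mm, max %.1f%% of rest, peak +%.2f m/s\n",
    x$muscle, x$rest_length_mm, max(x$pct_rest, na.rm = TRUE),
    x$max_speed_ms))
  invisible(x)
}

#' Export a muscle series as a data frame / CSV
#'
#' @param x a `muscle_series`.
#' @param path optional CSV path.
#' @return data frame with `frame`, `time`, `length_mm`, `pct_rest`,
#'   `speed_ms`, `pattern`.
#' @export
muscle_series_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "muscle_series"))
  n <- length(x$length_mm)
  df <- data.frame(frame = seq_len(n) - 1L, time = (seq_len(n) - 1L) / x$frame_rate,
                   length_mm = x$length_mm, pct_rest = x$pct_rest,
                   speed_ms = x$speed_ms, pattern = x$pattern,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
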