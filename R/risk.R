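#' Assess over-lengthening injury risk for one muscle
#'
#' Applies the repetitive-stress-injury criterion: a muscle is flagged at
#' risk when its maximal normalised length strictly exceeds the threshold
#' (default 120 percent of rest length).
#'
#' @param series a `muscle_series` (see [muscle_series()]), or a list with at
#'   least `muscle`, `pct_rest` and optionally `speed_ms`, `frame_rate`.
#' @param threshold risk threshold in percent of rest length.
#' @param rise_window,rise_factor forwarded to [detect_impact_like()].
#' @return object of class `risk_assessment`: `muscle`, `max_pct_rest`,
#'   `threshold`, `at_risk`, `peak_speed_ms`, `impact_like_events`.
#' @export
assess_risk <- function(series, threshold = 120, rise_window = 100,
                        rise_factor = 3) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive")
  pct <- series$pct_rest[is.finite(series$pct_rest)]
  if (length(pct) == 0)
    stop("muscle '", series$muscle, "' has no valid frames")
  mx <- max(pct)
  speed <- series$speed_ms
  peak <- if (is.null(speed)) NA_real_ else {
    pos <- speed[is.finite(speed) & speed > 0]
    if (length(pos) > 0) max(pos) else 0
  }
  events <- if (!is.null(speed) && !is.null(series$frame_rate))
    detect_impact_like(speed, series$frame_rate, rise_window, rise_factor)
  else list()
  structure(list(muscle = series$muscle, max_pct_rest = mx,
                 threshold = threshold, at_risk = mx > threshold,
                 peak_speed_ms = peak, impact_like_events = events),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("%-18s max %6.1f%% of rest  %s", x$muscle, x$max_pct_rest,
              if (x$at_risk) sprintf("AT RISK (> %g%%)", x$threshold)
              else "ok"))
  if (is.finite(x$peak_speed_ms))
    cat(sprintf("  peak %.2f m/s", x$peak_speed_ms))
  if (length(x$impact_like_events) > 0)
    cat(sprintf("  %d impact-like event(s)", length(x$impact_like_events)))
  cat("\n")
  invisible(x)
}

#' Rank muscles by maximal normalised lengthening
#'
#' @param assessments list of `risk_assessment` objects.
#' @return list with `ranked` (all assessments, descending by
#'   `max_pct_rest`) and `flagged` (the at-risk subset in the same order).
#' @export
rank_muscles <- function(assessments) {
  if (length(assessments) < 1) stop("no assessments to rank")
  ord <- order(vapply(assessments, function(a) a$max_pct_rest, numeric(1)),
               decreasing = TRUE)
  ranked <- assessments[ord]
  flagged <- ranked[vapply(ranked, function(a) a$at_risk, logical(1))]
  list(ranked = ranked, flagged = flagged)
}

#' Detect impact-like rises in lengthening speed
#'
#' An impact-like eccentric event is an abrupt rise of the lengthening
#' speed: from below a reference level to at least `rise_factor` times that
#' level within at most `rise_window` milliseconds, while the muscle is
#' lengthening (positive dL/dt). The reference level is the median of the
#' speed series; when that median is not positive (mixed
#' lengthening/shortening trials) the median of the positive part is used,
#' since a non-positive reference makes the rise criterion meaningless.
#'
#' @param speed_series numeric lengthening speed (m/s per frame).
#' @param frame_rate Hz.
#' @param rise_window maximal rise duration, ms.
#' @param rise_factor multiple of the reference level that must be reached.
#' @param min_ref noise floor (m/s): series whose reference level falls
#'   below it are treated as not lengthening at all (no events), so numeric
#'   ripple on an essentially constant-length muscle is never reported.
#' @return list of events, each with `start`, `end` (0-based frames),
#'   `duration_ms`, `from_ms`, `to_ms` and `rise_ms2` (mean speed rise in
#'   m/s^2). Empty list when no event (or a degenerate all-zero series).
#' @export
detect_impact_like <- function(speed_series, frame_rate, rise_window = 100,
                               rise_factor = 3, min_ref = 0.01) {
  s <- speed_series
  n <- length(s)
  wf <- max(1L, floor(rise_window / 1000 * frame_rate))
  if (n < 3) return(list())
  ref <- stats::median(s[is.finite(s)])
  if (!is.finite(ref) || ref <= 0) {
    pos <- s[is.finite(s) & s > 0]
    if (length(pos) == 0) return(list())
    ref <- stats::median(pos)
  }
  if (ref < min_ref) return(list())
  hi <- rise_factor * ref
  events <- list()
  f <- 1L
  while (f <= n - 1L) {
    if (is.finite(s[f]) && s[f] <= ref) {
      jmax <- min(n, f + wf)
      win <- (f + 1L):jmax
      cross <- win[which(is.finite(s[win]) & s[win] >= hi)]
      if (length(cross) > 0) {
        j <- cross[1]
        # anchor the event at the last at-or-below-reference frame before
        # the crossing, so it covers the jump itself
        below <- which(is.finite(s[f:(j - 1)]) & s[f:(j - 1)] <= ref)
        i <- f + below[length(below)] - 1L
        seg <- s[i:j]
        if (all(is.finite(seg)) && s[j] > 0 && mean(seg) > 0) {
          dur <- (j - i) / frame_rate
          events[[length(events) + 1]] <- list(
            start = i - 1L, end = j - 1L, duration_ms = dur * 1000,
            from_ms = s[i], to_ms = s[j],
            rise_ms2 = (s[j] - s[i]) / dur)
          f <- j + 1L                  # merge: skip past this rise
          next
        }
      }
    }
    f <- f + 1L
  }
  events
}

#' Segment a pitching trial into its seven events and six phases
#'
#' Event heuristics: balance point = peak lead-foot height; foot contact =
#' return of the lead foot to (near) its minimum height after the balance
#' point; maximum external / internal shoulder rotation = global extrema of
#' the shoulder axial-rotation angle; ball release = peak hand speed between
#' the two rotation extrema; initial and fielding positions = trial bounds.
#' The six phases (wind-up, stride, arm cocking, arm acceleration, arm
#' deceleration, follow-through) partition the interval between consecutive
#' events.
#'
#' @param shoulder_angles a `joint_angles` object for the throwing shoulder
#'   (its `rot` component is used).
#' @param hand_speed numeric per-frame hand speed, m/s.
#' @param lead_foot_height numeric per-frame lead-foot height, mm.
#' @param contact_frac fraction of the foot-height range above its minimum
#'   below which the foot counts as down again.
#' @return object of class `pitch_phases`: `events` (named integer vector of
#'   seven 0-based frames) and `phases` (data frame `phase`, `start`,
#'   `end`).
#' @export
segment_pitch_phases <- function(shoulder_angles, hand_speed,
                                 lead_foot_height, contact_frac = 0.05) {
  rot <- shoulder_angles$angles[, "rot"]
  n <- length(rot)
  if (length(hand_speed) != n || length(lead_foot_height) != n)
    stop("shoulder angles, hand speed and foot height must be aligned series")
  balance <- which.max(lead_foot_height)
  rng <- max(lead_foot_height) - min(lead_foot_height)
  thr <- min(lead_foot_height) + contact_frac * rng
  after <- which(seq_len(n) > balance & lead_foot_height <= thr)
  if (length(after) == 0)
    stop("segmentation error: lead foot never returns down after balance point")
  contact <- after[1]
  # extrema of the axial rotation; max external rotation is the minimum
  # (external rotation negative by convention), internal the maximum
  mer <- which.min(rot)
  mir <- which.max(rot)
  if (mer %in% c(1L, n) || mir %in% c(1L, n))
    stop("segmentation error: shoulder rotation is monotone (no interior extremum)")
  if (mer >= mir)
    stop("segmentation error: maximum external rotation (frame ", mer - 1L,
         ") does not precede maximum internal rotation (frame ", mir - 1L, ")")
  span <- mer:mir
  release <- span[which.max(hand_speed[span])]
  ev <- c(initial_position = 1L, balance_point = balance,
          foot_contact = contact, max_external_rotation = mer,
          ball_release = release, max_internal_rotation = mir,
          fielding_position = n)
  if (any(diff(ev) <= 0)) {
    bad <- names(ev)[c(FALSE, diff(ev) <= 0)]
    stop("segmentation error: events out of order at ",
         paste(bad, collapse = ", "))
  }
  phases <- data.frame(
    phase = c("wind_up", "stride", "arm_cocking", "arm_acceleration",
              "arm_deceleration", "follow_through"),
    start = ev[-length(ev)] - 1L, end = ev[-1] - 1L,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(events = ev - 1L, phases = phases), class = "pitch_phases")
}

#' @export
print.pitch_phases <- function(x, ...) {
  cat("pitch_phases: events at frames",
      paste(sprintf("%s=%d", names(x$events), x$events), collapse = ", "),
      "\n")
  invisible(x)
}
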