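# Axis rotation matrices, column-vector convention: p_global = R %*% p_local
rot_axis <- function(axis, deg) {
  t <- deg * pi / 180
  c <- cos(t); s <- sin(t)
  switch(axis,
    X = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
    Y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
    Z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3),
    stop("axis must be X, Y or Z"))
}

#' Compose a rotation from Cardan angles
#'
#' Intrinsic rotations applied in the order given by `sequence` (e.g. `"YXZ"`
#' = flexion/extension about Y, then abduction/adduction about X, then axial
#' rotation about Z).
#'
#' @param angles numeric length-3, degrees, in sequence order.
#' @param sequence one of the six three-distinct-axis Cardan sequences.
#' @return 3x3 rotation matrix.
#' @export
cardan_compose <- function(angles, sequence = "YXZ") {
  ax <- strsplit(sequence, "")[[1]]
  rot_axis(ax[1], angles[1]) %*% rot_axis(ax[2], angles[2]) %*%
    rot_axis(ax[3], angles[3])
}

#' Decompose a rotation into Cardan angles
#'
#' Inverse of [cardan_compose()]. Near gimbal lock (middle angle within
#' `gimbal_tol` degrees of +-90) the first and third axes align and the
#' decomposition is ill-conditioned; the angles are still returned, with
#' `gimbal = TRUE`.
#'
#' @param R 3x3 rotation matrix.
#' @inheritParams cardan_compose
#' @param gimbal_tol degrees from +-90 at which to raise the gimbal flag.
#' @return list with `angles` (degrees, sequence order) and `gimbal` flag.
#' @export
cardan_decompose <- function(R, sequence = "YXZ", gimbal_tol = 1) {
  ax <- match(strsplit(sequence, "")[[1]], c("X", "Y", "Z"))
  i <- ax[1]; j <- ax[2]; k <- ax[3]
  eps <- if (paste(c("X", "Y", "Z")[ax], collapse = "") %in%
             c("XYZ", "YZX", "ZXY")) 1 else -1
  s2 <- max(-1, min(1, eps * R[i, k]))
  t2 <- asin(s2)
  t1 <- atan2(-eps * R[j, k], R[k, k])
  t3 <- atan2(-eps * R[i, j], R[i, i])
  deg <- c(t1, t2, t3) * 180 / pi
  list(angles = deg, gimbal = abs(abs(deg[2]) - 90) < gimbal_tol)
}

#' Least-squares rigid pose of one segment from its markers
#'
#' Kabsch/SVD superposition: finds the proper rotation `R` and translation
#' `t` minimising the RMS distance between `R p_i + t` and the observed
#' marker positions, with a determinant guard against reflections. No
#' scaling is fitted.
#'
#' @param observed numeric `n x 3` matrix of global marker positions (mm),
#'   rows named by marker label; rows with non-finite values are dropped.
#' @param template a segment definition (element of
#'   `skeleton_model$segments`) whose `markers` matrix gives the local
#'   template, or a bare `n x 3` matrix with matching row names.
#' @return list with `R` (3x3, local to global), `t` (length-3, mm),
#'   `residual` (RMS marker distance, mm), `n_markers` used, and `valid`.
#'   When fewer than 3 usable markers are shared, `valid` is `FALSE` and the
#'   pose entries are `NA`.
#' @export
fit_segment_pose <- function(observed, template) {
  tm <- if (is.list(template)) template$markers else template
  seg_name <- if (is.list(template)) template$name else "segment"
  common <- intersect(rownames(tm), rownames(observed))
  obs <- observed[common, , drop = FALSE]
  ok <- apply(obs, 1, function(v) all(is.finite(v)))
  common <- common[ok]
  if (length(common) < 3)
    return(list(R = matrix(NA_real_, 3, 3), t = rep(NA_real_, 3),
                residual = NA_real_, n_markers = length(common),
                valid = FALSE))
  P <- tm[common, , drop = FALSE]
  Q <- observed[common, , drop = FALSE]
  if (qr(scale(P, scale = FALSE))$rank < 2)
    stop("degenerate geometry: usable template markers of '", seg_name,
         "' are collinear")
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cq - R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t, "+")
  residual <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t, residual = residual, n_markers = length(common),
       valid = TRUE)
}

#' Fit per-frame segment poses for a whole trial
#'
#' Runs [fit_segment_pose()] on every frame for every segment of the model.
#' Frames with fewer than 3 usable markers for a segment are marked invalid
#' for that segment.
#'
#' @param series a [marker_series] (gap-filled and smoothed, normally).
#' @param model a `skeleton_model`.
#' @return named list of `pose_series` objects, one per segment, each with
#'   fields `R` (3x3xN array), `t` (`N x 3`), `residual`, `valid`,
#'   `frame_rate`.
#' @export
fit_poses <- function(series, model) {
  stopifnot(inherits(series, "marker_series"), inherits(model, "skeleton_model"))
  nf <- series$n_frames
  out <- list()
  for (seg in model$segments) {
    labs <- intersect(rownames(seg$markers), series$labels)
    idx <- match(labs, series$labels)
    R <- array(NA_real_, dim = c(3, 3, nf))
    tt <- matrix(NA_real_, nf, 3)
    resid <- rep(NA_real_, nf)
    valid <- rep(FALSE, nf)
    for (f in seq_len(nf)) {
      obs <- series$positions[f, , idx, drop = FALSE]
      dim(obs) <- c(3, length(idx))
      obs <- t(obs)
      rownames(obs) <- labs
      obs[series$missing[f, idx], ] <- NA_real_
      fit <- fit_segment_pose(obs, seg)
      if (fit$valid) {
        R[, , f] <- fit$R; tt[f, ] <- fit$t
        resid[f] <- fit$residual; valid[f] <- TRUE
      }
    }
    out[[seg$name]] <- structure(
      list(segment = seg$name, R = R, t = tt, residual = resid,
           valid = valid, frame_rate = series$frame_rate, n_frames = nf),
      class = "pose_series")
  }
  out
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("pose_series '%s': %d frames, %d valid, mean residual %.3f mm\n",
              x$segment, x$n_frames, sum(x$valid),
              mean(x$residual, na.rm = TRUE)))
  invisible(x)
}

# remove +-360 degree jumps between adjacent samples
unwrap_degrees <- function(a) {
  if (length(a) < 2) return(a)
  d <- diff(a)
  steps <- -360 * round(d / 360)
  a + c(0, cumsum(steps))
}

#' Joint angles between two segments
#'
#' Decomposes the relative rotation `R_rel = t(R_parent) %*% R_child` per
#' frame in the given Cardan sequence, reporting the three clinical
#' components (flexion/extension, abduction/adduction, axial rotation for
#' the default `"YXZ"` sequence), in degrees, unwrapped over time so no
#' +-180 degree jumps remain between adjacent frames.
#'
#' @param parent,child `pose_series` for the two segments (equal length).
#' @param sequence Cardan sequence (see [cardan_compose()]).
#' @param joint label for the joint.
#' @return object of class `joint_angles`: fields `joint`, `angles`
#'   (`N x 3` matrix, columns `fe`, `aa`, `rot`), `sequence`, `gimbal`
#'   (per-frame warning flag), `valid`, `frame_rate`.
#' @export
compute_joint_angles <- function(parent, child, sequence = "YXZ",
                                 joint = child$segment) {
  stopifnot(inherits(parent, "pose_series"), inherits(child, "pose_series"))
  if (parent$n_frames != child$n_frames)
    stop("parent and child pose series have different frame counts")
  nf <- parent$n_frames
  ang <- matrix(NA_real_, nf, 3, dimnames = list(NULL, c("fe", "aa", "rot")))
  gimbal <- rep(FALSE, nf)
  valid <- parent$valid & child$valid
  for (f in which(valid)) {
    Rrel <- t(parent$R[, , f]) %*% child$R[, , f]
    dec <- cardan_decompose(Rrel, sequence)
    ang[f, ] <- dec$angles
    gimbal[f] <- dec$gimbal
  }
  for (c in 1:3) {
    v <- which(valid)
    if (length(v) > 1) ang[v, c] <- unwrap_degrees(ang[v, c])
  }
  structure(list(joint = joint, angles = ang, sequence = sequence,
                 gimbal = gimbal, valid = valid,
                 frame_rate = parent$frame_rate),
            class = "joint_angles")
}

#' @export
print.joint_angles <- function(x, ...) {
  cat(sprintf("joint_angles '%s' (%s): %d frames", x$joint, x$sequence,
              nrow(x$angles)))
  if (any(x$gimbal)) cat(sprintf(", %d gimbal-flagged", sum(x$gimbal)))
  cat("\n")
  for (c in colnames(x$angles))
    cat(sprintf("  %-3s ROM %.1f deg\n", c,
                compute_rom(x$angles[x$valid, c])))
  invisible(x)
}

#' Range of motion of an angle sequence
#'
#' ROM = maximum - minimum over the analysed interval.
#'
#' @param angles numeric vector of per-frame angles (degrees).
#' @return ROM in degrees.
#' @export
compute_rom <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) == 0) stop("cannot compute ROM of an empty interval")
  max(angles) - min(angles)
}

#' Angular velocity of an angle series
#'
#' Central-difference derivative (one-sided at the edges), with the peak
#' speed and the steepest sustained deceleration interval: the decline of
#' `|omega|` from its global peak to the next local minimum.
#'
#' @param angles numeric per-frame angles (degrees).
#' @param frame_rate Hz.
#' @return list with `omega` (deg/s per frame), `peak` (max `|omega|`),
#'   `peak_frame` (0-based), and `deceleration`: list with `start`, `end`
#'   (0-based frames), `duration_s`, `drop_deg_s` and `rate_deg_s2`.
#' @export
angular_velocity <- function(angles, frame_rate) {
  n <- length(angles)
  if (n < 3) stop("angular velocity needs at least 3 frames")
  dt <- 1 / frame_rate
  omega <- numeric(n)
  omega[1] <- (angles[2] - angles[1]) / dt
  omega[n] <- (angles[n] - angles[n - 1]) / dt
  omega[2:(n - 1)] <- (angles[3:n] - angles[1:(n - 2)]) / (2 * dt)
  sp <- abs(omega)
  pk <- which.max(sp)
  end <- pk
  while (end < n && sp[end + 1] < sp[end]) end <- end + 1
  dec <- list(start = pk - 1L, end = end - 1L,
              duration_s = (end - pk) * dt,
              drop_deg_s = sp[pk] - sp[end],
              rate_deg_s2 = if (end > pk) (sp[pk] - sp[end]) / ((end - pk) * dt)
                            else 0)
  list(omega = omega, peak = sp[pk], peak_frame = pk - 1L, deceleration = dec)
}

#' Export a joint-angle series as a data frame / CSV
#'
#' @param x a `joint_angles` object.
#' @param path optional CSV path; when given the table is also written.
#' @return data frame with `frame`, `time`, `fe`, `aa`, `rot`, `gimbal`,
#'   `valid`.
#' @export
joint_angles_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "joint_angles"))
  nf <- nrow(x$angles)
  df <- data.frame(frame = seq_len(nf) - 1L,
                   time = (seq_len(nf) - 1L) / x$frame_rate,
                   fe = x$angles[, "fe"], aa = x$angles[, "aa"],
                   rot = x$angles[, "rot"], gimbal = x$gimbal,
                   valid = x$valid)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
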