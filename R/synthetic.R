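#' Build a motion script
#'
#' A motion script prescribes one synthetic trial: per-joint angle curves,
#' duration, frame rate, marker noise and occlusions. Curves are given per
#' (non-root) segment as a list with components `fe`, `aa`, `rot`; each
#' component is either
#' \itemize{
#'   \item a list `list(values =, times =, excursion =)`: a natural cubic
#'     spline through the control `values` (at `times` in [0, 1] fractions
#'     of the trial, equally spaced when omitted), affinely rescaled after
#'     sampling so its realised range equals `excursion` degrees exactly;
#'   \item a function of the normalised time vector, returning degrees
#'     (used by the pitch preset to pin its event timing); or
#'   \item a single number (constant angle).
#' }
#' Omitted components and segments are held at zero.
#'
#' @param skill label (`instep_kick`, `fan_kick`, `axe_kick`, `pitch`,
#'   `custom`).
#' @param duration trial duration, s.
#' @param frame_rate Hz.
#' @param curves named list of per-segment curve lists.
#' @param noise_sd isotropic marker noise SD, mm.
#' @param occlusions list of `list(marker =, start =, end =)` 0-based frame
#'   intervals to blank out.
#' @param seed integer seed for the noise generator.
#' @return object of class `motion_script`.
#' @export
motion_script <- function(skill = "custom", duration = 1, frame_rate = 200,
                          curves = list(), noise_sd = 0, occlusions = list(),
                          seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  structure(list(skill = skill, duration = duration, frame_rate = frame_rate,
                 curves = curves, noise_sd = noise_sd,
                 occlusions = occlusions, seed = as.integer(seed)),
            class = "motion_script")
}

#' @export
print.motion_script <- function(x, ...) {
  cat(sprintf("motion_script '%s': %.2f s @ %g Hz, noise %.2g mm, %d joint(s) scripted\n",
              x$skill, x$duration, x$frame_rate, x$noise_sd, length(x$curves)))
  invisible(x)
}

# evaluate one curve component on the normalised time grid
eval_curve <- function(cv, t01) {
  n <- length(t01)
  if (is.null(cv)) return(numeric(n))
  if (is.function(cv)) return(cv(t01))
  if (is.numeric(cv) && length(cv) == 1) return(rep(cv, n))
  if (is.numeric(cv)) {
    if (length(cv) != n) stop("sampled curve has wrong length")
    return(cv)
  }
  vals <- as.numeric(cv$values)
  times <- if (is.null(cv$times)) seq(0, 1, length.out = length(vals))
           else as.numeric(cv$times)
  f <- stats::splinefun(times, vals, method = "natural")
  y <- f(t01)
  if (!is.null(cv$excursion)) {
    r <- max(y) - min(y)
    if (r > 0) y <- y * (cv$excursion / r)
  }
  y
}

# raised-cosine segment helpers used by the pitch preset
cos_ramp <- function(t, t0, t1, v0, v1) {
  w <- pmin(1, pmax(0, (t - t0) / (t1 - t0)))
  v0 + (v1 - v0) * (1 - cos(pi * w)) / 2
}

#' Curated preset scripts for the four studied skills
#'
#' Joint excursions default to the reported group means for each skill
#' (e.g. hip flexion/extension 129 deg for the instep kick, 146.3 vs 162.2
#' deg for fan vs axe kick, knee 108.9 vs 65.3 deg); they demonstrate the
#' skills' kinematic envelopes, they do not reproduce any subject's trial.
#' The pitch preset scripts the throwing shoulder's axial rotation and the
#' lead leg so that the seven pitching events are recoverable:
#' balance point at 25 percent of the trial, foot contact at 40 percent,
#' maximum external / internal shoulder rotation at 55 / 65 percent with
#' the hand-speed peak between them.
#'
#' @param skill one of `"instep_kick"`, `"fan_kick"`, `"axe_kick"`,
#'   `"pitch"`.
#' @param overrides named list merged over the preset's defaults
#'   (e.g. `list(noise_sd = 1)`).
#' @return a [motion_script].
#' @export
preset_script <- function(skill, overrides = list()) {
  presets <- c("instep_kick", "fan_kick", "axe_kick", "pitch")
  if (!skill %in% presets)
    stop("unknown skill '", skill, "'; available presets: ",
         paste(presets, collapse = ", "))
  # aa is the middle Cardan angle: its shapes are kept near zero-mean so the
  # scaled curve stays well clear of the +-90 deg gimbal region
  kick_curves <- function(hip, knee) list(
    thigh_r = list(
      fe  = list(values = c(0, 15, -75, 25, 5), excursion = hip[1]),
      aa  = list(values = c(0, 40, -40, 15, 0), excursion = hip[2]),
      rot = list(values = c(0, -20, -60, -10, 0), excursion = hip[3])),
    shank_r = list(
      fe  = list(values = c(0, 40, 90, 15, 5), excursion = knee[1]),
      aa  = list(values = c(0, 15, -25, 10, 0), excursion = knee[2]),
      rot = list(values = c(0, 10, 35, 5, 0), excursion = knee[3])),
    upper_trunk = list(
      fe  = list(values = c(0, -8, 6, 2, 0), excursion = 15),
      aa  = list(values = c(0, 4, -4, 0, 0), excursion = 8)))
  args <- switch(skill,
    instep_kick = list(skill = skill, duration = 1.2,
                       curves = kick_curves(c(129, 26, 17), c(113, 23, 19))),
    fan_kick = list(skill = skill, duration = 2.0,
                    curves = kick_curves(c(146.3, 87.8, 54.1),
                                         c(108.9, 27.4, 28.2))),
    axe_kick = list(skill = skill, duration = 1.0,
                    curves = kick_curves(c(162.2, 51.6, 57.9),
                                         c(65.3, 28.8, 21.5))),
    pitch = list(skill = skill, duration = 2.0, curves = list(
      # lead (left) hip: raised-cosine knee lift peaking at t = 0.25,
      # back down (and flat) from t = 0.40 on
      thigh_l = list(fe = function(t)
        ifelse(t <= 0.25, cos_ramp(t, 0, 0.25, 0, -60),
        ifelse(t <= 0.40, cos_ramp(t, 0.25, 0.40, -60, 0), 0))),
      # throwing shoulder axial rotation: external to -170 deg at t = 0.55,
      # whip to +50 deg at t = 0.65 (hand-speed peak at 0.60), ease out.
      # Each extremum sits in a symmetric parabolic cap wider than the
      # smoothing kernel, so its frame survives the five-point filter.
      upper_arm_r = list(rot = function(t)
        ifelse(t <= 0.5375, cos_ramp(t, 0, 0.5375, 0, -168),
        ifelse(t <= 0.5625, -170 + 12800 * (t - 0.55)^2,
        ifelse(t <= 0.6375, cos_ramp(t, 0.5625, 0.6375, -168, 48),
        ifelse(t <= 0.6625, 50 - 12800 * (t - 0.65)^2,
               cos_ramp(t, 0.6625, 1, 48, 20)))))))))
  args <- utils::modifyList(args, overrides)
  do.call(motion_script, args)
}

#' Generate a synthetic trial by forward kinematics
#'
#' Composes segment poses down the joint tree from the script's prescribed
#' angle curves, transforms each segment's owned template markers to global
#' coordinates, then applies seeded isotropic Gaussian noise and the
#' scripted occlusions. The returned ground truth (prescribed angles, true
#' poses, muscle lengths computed from the true poses, and pitch events) is
#' independent of the marker-fitting pipeline, so it can serve as an oracle
#' for it.
#'
#' @param script a [motion_script].
#' @param model a `skeleton_model`.
#' @param muscles optional named list of [muscle_path]s for which ground
#'   truth length series are computed.
#' @return list with `series` (a [marker_series]) and `ground_truth`: a list
#'   with `angles` (named list of `N x 3` matrices, degrees), `poses`
#'   (named list of true `pose_series`), `muscle_lengths` (named list of
#'   `muscle_series`), and for pitch scripts `events` (0-based frames).
#' @export
generate_motion <- function(script, model, muscles = NULL) {
  stopifnot(inherits(script, "motion_script"), inherits(model, "skeleton_model"))
  unknown <- setdiff(names(script$curves), names(model$segments))
  if (length(unknown) > 0)
    stop("script curves reference unknown segment(s): ",
         paste(unknown, collapse = ", "))
  nf <- round(script$duration * script$frame_rate) + 1L
  t01 <- (seq_len(nf) - 1) / (nf - 1)
  angles <- list()
  for (nm in names(model$segments)) {
    if (nm == model$root) next
    cv <- script$curves[[nm]]
    angles[[nm]] <- cbind(fe = eval_curve(cv$fe, t01),
                          aa = eval_curve(cv$aa, t01),
                          rot = eval_curve(cv$rot, t01))
  }
  # forward kinematics down the tree
  poses <- list()
  for (nm in model$order) {
    s <- model$segments[[nm]]
    R <- array(NA_real_, dim = c(3, 3, nf))
    tt <- matrix(NA_real_, nf, 3)
    if (is.na(s$parent)) {
      for (f in seq_len(nf)) R[, , f] <- diag(3)
      tt[] <- matrix(s$joint_offset, nf, 3, byrow = TRUE)
    } else {
      pp <- poses[[s$parent]]
      for (f in seq_len(nf)) {
        Rj <- cardan_compose(angles[[nm]][f, ], s$sequence)
        R[, , f] <- pp$R[, , f] %*% Rj
        tt[f, ] <- pp$t[f, ] + as.numeric(pp$R[, , f] %*% s$joint_offset)
      }
    }
    poses[[nm]] <- structure(
      list(segment = nm, R = R, t = tt, residual = rep(0, nf),
           valid = rep(TRUE, nf), frame_rate = script$frame_rate,
           n_frames = nf),
      class = "pose_series")
  }
  # markers from their owning segments
  labels <- model$marker_labels
  pos <- array(NA_real_, dim = c(nf, 3, length(labels)))
  for (nm in model$order) {
    s <- model$segments[[nm]]
    ps <- poses[[nm]]
    for (lab in s$owns) {
      li <- match(lab, labels)
      local <- s$markers[lab, ]
      for (f in seq_len(nf))
        pos[f, , li] <- as.numeric(ps$R[, , f] %*% local) + ps$t[f, ]
    }
  }
  miss <- matrix(FALSE, nf, length(labels))
  if (script$noise_sd > 0) {
    rs <- .Random.seed_save()
    set.seed(script$seed)
    pos <- pos + array(stats::rnorm(length(pos), sd = script$noise_sd),
                       dim = dim(pos))
    .Random.seed_restore(rs)
  }
  for (oc in script$occlusions) {
    li <- match(oc$marker, labels)
    if (is.na(li)) stop("occlusion references unknown marker: ", oc$marker)
    fr <- (oc$start:oc$end) + 1L
    fr <- fr[fr >= 1 & fr <= nf]
    miss[fr, li] <- TRUE
    pos[fr, , li] <- NA_real_
  }
  series <- marker_series(pos, labels, script$frame_rate, miss)

  gt <- list(angles = angles, poses = poses)
  if (!is.null(muscles)) {
    gt$muscle_lengths <- lapply(muscles, function(mp)
      muscle_series(mp, poses, model = model))
  }
  if (script$skill == "pitch") {
    ja <- structure(list(joint = "upper_arm_r",
                         angles = angles[["upper_arm_r"]],
                         sequence = model$segments[["upper_arm_r"]]$sequence,
                         gimbal = rep(FALSE, nf), valid = rep(TRUE, nf),
                         frame_rate = script$frame_rate),
                    class = "joint_angles")
    hs <- hand_speed_from_poses(poses, model, "MC3_R")
    fh <- marker_height_from_poses(poses, model, "TOE_L")
    gt$events <- segment_pitch_phases(ja, hs, fh)$events
  }
  list(series = series, ground_truth = gt)
}

# speed (m/s) of one marker computed from true poses
hand_speed_from_poses <- function(poses, model, label) {
  seg <- owner_of(model, label)
  ps <- poses[[seg]]
  local <- model$segments[[seg]]$markers[label, ]
  nf <- ps$n_frames
  p <- t(vapply(seq_len(nf), function(f)
    as.numeric(ps$R[, , f] %*% local) + ps$t[f, ], numeric(3)))
  speed_from_trajectory(p, ps$frame_rate)
}

marker_height_from_poses <- function(poses, model, label) {
  seg <- owner_of(model, label)
  ps <- poses[[seg]]
  local <- model$segments[[seg]]$markers[label, ]
  vapply(seq_len(ps$n_frames), function(f)
    (as.numeric(ps$R[, , f] %*% local) + ps$t[f, ])[3], numeric(1))
}

owner_of <- function(model, label) {
  for (s in model$segments) if (label %in% s$owns) return(s$name)
  stop("no segment owns marker '", label, "'")
}

#' Speed of a 3D trajectory
#'
#' Central-difference speed magnitude of an `N x 3` position series (mm),
#' returned in m/s.
#'
#' @param p numeric `N x 3` matrix, mm.
#' @param frame_rate Hz.
#' @return numeric vector of speeds, m/s.
#' @export
speed_from_trajectory <- function(p, frame_rate) {
  n <- nrow(p)
  if (n < 3) stop("speed needs at least 3 frames")
  v <- matrix(NA_real_, n, 3)
  v[1, ] <- (p[2, ] - p[1, ]) * frame_rate
  v[n, ] <- (p[n, ] - p[n - 1, ]) * frame_rate
  v[2:(n - 1), ] <- (p[3:n, ] - p[1:(n - 2), ]) * frame_rate / 2
  sqrt(rowSums(v^2)) / 1000
}

# save/restore the global RNG state so seeded noise does not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
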