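#' Published group summaries for the four studied skills
#'
#' Group means, SDs and sizes (mean over subjects of per-subject trial
#' means) reported for the instep kick, fan kick, axe kick and baseball
#' pitch: joint ROM components (degrees), maximal muscle lengthening
#' (percent of rest length) and lengthening speed (m/s). Bundled as inputs
#' for worked examples — risk flagging of the reported means and
#' between-skill significance tests — since the underlying recordings were
#' never deposited.
#'
#' @param skill optional filter: one of `"instep_kick"`, `"fan_kick"`,
#'   `"axe_kick"`, `"pitch"`.
#' @param measure optional filter: `"rom"`, `"max_lengthening"`,
#'   `"lengthening_speed"`, `"peak_deceleration"`.
#' @return data frame with columns `skill`, `measure`, `item`, `component`,
#'   `mean`, `sd`, `n`.
#' @export
reference_summaries <- function(skill = NULL, measure = NULL) {
  path <- system.file("extdata", "skill_reference_summaries.csv",
                      package = "kinerisk", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(component = "character"))
  if (!is.null(skill)) df <- df[df$skill %in% skill, ]
  if (!is.null(measure)) df <- df[df$measure %in% measure, ]
  rownames(df) <- NULL
  df
}

# default parent->child joint pairs reported by run_analysis, with the
# conventional joint names
default_joints <- function(model) {
  segs <- setdiff(model$order, model$root)
  nice <- c(thigh_r = "hip_r", thigh_l = "hip_l", shank_r = "knee_r",
            shank_l = "knee_l", foot_r = "ankle_r", foot_l = "ankle_l",
            upper_arm_r = "shoulder_r", upper_arm_l = "shoulder_l",
            forearm_r = "elbow_r", forearm_l = "elbow_l",
            hand_r = "wrist_r", hand_l = "wrist_l",
            upper_trunk = "lumbar", head = "neck")
  stats::setNames(ifelse(segs %in% names(nice), nice[segs], segs), segs)
}

#' Run the full single-trial analysis
#'
#' Orchestrates the pipeline: read the trial, fill occlusion gaps, apply
#' the 1-3-4-3-1 smoothing filter, fit per-frame segment poses, compute
#' joint angles and ROM, track every configured muscle's length against its
#' rest length, and assess over-lengthening risk. For pitch trials the
#' seven-event / six-phase segmentation is added. The run is deterministic
#' given its inputs; outputs are written only after the whole analysis
#' succeeds.
#'
#' @param input a [marker_series], or a path to a TRC / C3D / long-CSV
#'   trial file (dispatched on extension).
#' @param config a model configuration as returned by [load_model_config()]
#'   (default: the bundled full-body model).
#' @param skill optional skill label; `"pitch"` enables phase segmentation.
#' @param smoothing apply the five-point filter (on by default).
#' @param gap_limit longest occlusion gap (frames) interpolated by
#'   [fill_gaps()].
#' @param threshold risk threshold, percent of rest length.
#' @param out_dir optional directory; when given, `rom.csv`, `muscles.csv`,
#'   `report.json` (and `phases.csv` for pitch trials) are written there.
#' @return list of class `kinerisk_report`: `rom_table`, `muscle_table`,
#'   `assessments`, `ranked`, `flagged`, `angles`, `muscle_series`,
#'   `poses`, `gap_report`, and `phases` (pitch only).
#' @export
run_analysis <- function(input, config = default_model(), skill = NULL,
                         smoothing = TRUE, gap_limit = 10, threshold = 120,
                         out_dir = NULL) {
  series <- if (inherits(input, "marker_series")) input else {
    ext <- tolower(tools::file_ext(input))
    switch(ext,
           trc = read_trc(input),
           c3d = read_c3d(input),
           csv = read_marker_csv(input),
           stop("unrecognised trial file extension: .", ext))
  }
  model <- config$model
  muscles <- config$muscles
  filled <- fill_gaps(series, max_gap = gap_limit)
  gap_report <- attr(filled, "gap_report")
  proc <- if (smoothing) smooth_markers(filled) else filled
  poses <- fit_poses(proc, model)

  joints <- default_joints(model)
  angles <- list()
  rom_rows <- list()
  for (seg in names(joints)) {
    sdef <- model$segments[[seg]]
    ja <- compute_joint_angles(poses[[sdef$parent]], poses[[seg]],
                               sdef$sequence, joint = joints[[seg]])
    angles[[joints[[seg]]]] <- ja
    av <- ja$angles[ja$valid, , drop = FALSE]
    rom_rows[[joints[[seg]]]] <- data.frame(
      joint = joints[[seg]],
      fe = compute_rom(av[, "fe"]), aa = compute_rom(av[, "aa"]),
      rot = compute_rom(av[, "rot"]))
  }
  rom_table <- do.call(rbind, rom_rows)
  rownames(rom_table) <- NULL

  msr <- lapply(muscles, function(mp) muscle_series(mp, poses, model = model))
  assessments <- lapply(msr, assess_risk, threshold = threshold)
  ranking <- rank_muscles(assessments)
  muscle_table <- do.call(rbind, lapply(ranking$ranked, function(a)
    data.frame(muscle = a$muscle, max_pct_rest = a$max_pct_rest,
               at_risk = a$at_risk, peak_speed_ms = a$peak_speed_ms,
               n_impact_events = length(a$impact_like_events))))
  rownames(muscle_table) <- NULL

  report <- list(rom_table = rom_table, muscle_table = muscle_table,
                 assessments = assessments, ranked = ranking$ranked,
                 flagged = ranking$flagged, angles = angles,
                 muscle_series = msr, poses = poses,
                 gap_report = gap_report, threshold = threshold,
                 skill = skill)
  if (identical(skill, "pitch")) {
    sh <- angles[["shoulder_r"]]
    hs <- speed_from_trajectory(marker_xyz(proc, "MC3_R"), proc$frame_rate)
    fh <- marker_xyz(proc, "TOE_L")[, "z"]
    report$phases <- segment_pitch_phases(sh, hs, fh)
  }
  class(report) <- "kinerisk_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rom_table, file.path(out_dir, "rom.csv"),
                     row.names = FALSE)
    utils::write.csv(muscle_table, file.path(out_dir, "muscles.csv"),
                     row.names = FALSE)
    if (!is.null(report$phases))
      utils::write.csv(report$phases$phases, file.path(out_dir, "phases.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(threshold = threshold, rom = rom_table, muscles = muscle_table,
           flagged = vapply(ranking$flagged, function(a) a$muscle,
                            character(1)),
           events = if (!is.null(report$phases))
             as.list(report$phases$events) else NULL),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' @export
print.kinerisk_report <- function(x, ...) {
  cat("kinerisk_report\n\nJoint ROM (deg):\n")
  print(x$rom_table, digits = 4)
  cat(sprintf("\nMuscle lengthening (threshold %g%% of rest):\n", x$threshold))
  print(x$muscle_table, digits = 4)
  if (!is.null(x$phases)) { cat("\n"); print(x$phases) }
  invisible(x)
}

#' Aggregate repeated trials into group summaries
#'
#' Per-subject value = mean over that subject's trials; group summary =
#' mean and SD over subjects, per variable.
#'
#' @param df data frame with columns `subject`, `variable`, `value` (one
#'   row per trial).
#' @return data frame with `variable`, `mean`, `sd`, `n`.
#' @export
aggregate_trials <- function(df) {
  stopifnot(all(c("subject", "variable", "value") %in% names(df)))
  per_subj <- stats::aggregate(value ~ subject + variable, df, mean)
  out <- do.call(rbind, lapply(split(per_subj, per_subj$variable),
    function(g) data.frame(variable = g$variable[1], mean = mean(g$value),
                           sd = stats::sd(g$value), n = nrow(g))))
  rownames(out) <- NULL
  out
}

#' Compare two groups variable by variable
#'
#' Independent two-sample t-tests for every shared variable. Each group is
#' given either as raw trial-level values (columns `variable`, `value`,
#' optionally `subject` — aggregated per subject first) or as printed
#' summaries (columns `variable`, `mean`, `sd`, `n`).
#'
#' @param a,b data frames as described above.
#' @param alpha significance level.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param labels length-2 character: group names for the output columns.
#' @return data frame with one row per variable: group means, SDs, ns, `t`,
#'   `df`, `p`, `significant`.
#' @export
run_comparison <- function(a, b, alpha = 0.05,
                           variant = c("pooled", "welch"),
                           labels = c("a", "b")) {
  variant <- match.arg(variant)
  to_summary <- function(df) {
    if (all(c("mean", "sd", "n") %in% names(df))) {
      df[, c("variable", "mean", "sd", "n")]
    } else if (all(c("variable", "value") %in% names(df))) {
      if (!"subject" %in% names(df))
        df$subject <- seq_len(nrow(df))
      aggregate_trials(df)
    } else stop("each group needs columns variable+mean+sd+n or variable+value")
  }
  sa <- to_summary(a); sb <- to_summary(b)
  only_a <- setdiff(sa$variable, sb$variable)
  only_b <- setdiff(sb$variable, sa$variable)
  if (length(only_a) > 0 || length(only_b) > 0)
    stop("variable sets differ between groups; missing counterparts for: ",
         paste(c(only_a, only_b), collapse = ", "))
  rows <- lapply(sa$variable, function(v) {
    g1 <- sa[sa$variable == v, ]; g2 <- sb[sb$variable == v, ]
    tt <- t_test_from_summary(
      group_summary(g1$mean, g1$sd, g1$n),
      group_summary(g2$mean, g2$sd, g2$n), variant = variant, alpha = alpha)
    out <- data.frame(variable = v, g1$mean, g1$sd, g1$n, g2$mean, g2$sd,
                      g2$n, t = tt$t, df = tt$df, p = tt$p,
                      significant = tt$significant)
    names(out)[2:7] <- paste(rep(labels, each = 3), c("mean", "sd", "n"),
                             sep = "_")
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
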