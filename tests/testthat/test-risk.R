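fake_series <- function(name, pct, speed = NULL, frame_rate = 200) {
  list(muscle = name, pct_rest = pct, speed_ms = speed,
       frame_rate = frame_rate)
}

test_that("risk flag applies the strict >120% criterion", {
  expect_true(assess_risk(fake_series("add_mag", c(100, 174.6)))$at_risk)
  expect_false(assess_risk(fake_series("rect_fem", c(100, 112.8)))$at_risk)
  expect_false(assess_risk(fake_series("edge", c(100, 120.0)))$at_risk)
  expect_true(assess_risk(fake_series("edge", c(100, 120.0001)))$at_risk)
  expect_error(assess_risk(fake_series("empty", NA_real_)), "no valid frames")
  expect_error(assess_risk(fake_series("x", 130), threshold = -1), "positive")
})

test_that("raising the threshold never flags more muscles", {
  set.seed(4)
  for (i in 1:20) {
    pct <- runif(8, 90, 200)
    flags <- vapply(c(110, 120, 140, 180), function(th)
      sum(vapply(pct, function(p)
        assess_risk(fake_series("m", p), threshold = th)$at_risk,
        logical(1))) + 0, numeric(1))
    expect_true(all(diff(flags) <= 0))
  }
})

test_that("ranking orders by max lengthening and preserves membership", {
  ref <- reference_summaries("instep_kick", "max_lengthening")
  assessments <- lapply(seq_len(nrow(ref)), function(i)
    assess_risk(fake_series(ref$item[i], ref$mean[i])))
  rk <- rank_muscles(assessments)
  expect_setequal(vapply(rk$ranked, `[[`, "", "muscle"), ref$item)
  expect_equal(vapply(rk$flagged, `[[`, "", "muscle"),
               c("adductor_magnus", "gracilis", "semimembranosus"))
  got <- vapply(rk$ranked, function(a) a$max_pct_rest, numeric(1))
  expect_true(all(diff(got) <= 0))

  axe <- reference_summaries("axe_kick", "max_lengthening")
  rk2 <- rank_muscles(lapply(seq_len(nrow(axe)), function(i)
    assess_risk(fake_series(axe$item[i], axe$mean[i]))))
  expect_length(rk2$flagged, 4)

  low <- rank_muscles(list(assess_risk(fake_series("a", 101)),
                           assess_risk(fake_series("b", 119))))
  expect_length(low$flagged, 0)
})

test_that("impact-like detection finds abrupt eccentric rises only", {
  fr <- 200
  expect_length(detect_impact_like(rep(0.05, 200), fr), 0)
  expect_length(detect_impact_like(rep(0, 200), fr), 0)

  # 0.05 m/s baseline jumping to 0.6 m/s over 60 ms of lengthening
  jump <- c(rep(0.05, 100), seq(0.05, 0.6, length.out = 12), rep(0.6, 30),
            rep(0.05, 60))
  ev <- detect_impact_like(jump, fr, rise_window = 100, rise_factor = 3)
  expect_length(ev, 1)
  expect_true(ev[[1]]$start >= 99 && ev[[1]]$end <= 112)
  expect_gt(ev[[1]]$rise_ms2, 0)

  # same magnitude change while shortening: no event
  expect_length(detect_impact_like(-jump, fr), 0)
  # monotone decreasing speed: no event
  expect_length(detect_impact_like(seq(0.8, 0.01, length.out = 200), fr), 0)
})

test_that("pitch segmentation recovers generator events and partitions the trial", {
  cfg <- default_model()
  g <- generate_motion(preset_script("pitch"), cfg$model)
  rep <- run_analysis(g$series, cfg, skill = "pitch")
  expect_true(all(abs(rep$phases$events - g$ground_truth$events) <= 2))
  ph <- rep$phases$phases
  expect_equal(nrow(ph), 6)
  expect_equal(ph$start[-1], ph$end[-6])   # contiguous, non-overlapping
  expect_equal(ph$start[1], 0)
  expect_equal(ph$end[6], n_frames(g$series) - 1)
  expect_true(all(diff(rep$phases$events) > 0))
})

test_that("segmentation rejects degenerate rotation input", {
  nf <- 100
  ja <- structure(list(joint = "shoulder",
                       angles = cbind(fe = rep(0, nf), aa = rep(0, nf),
                                      rot = seq(0, 90, length.out = nf)),
                       sequence = "YXZ", gimbal = rep(FALSE, nf),
                       valid = rep(TRUE, nf), frame_rate = 200),
                  class = "joint_angles")
  foot <- c(seq(0, 100, length.out = 50), seq(100, 0, length.out = 50))
  expect_error(segment_pitch_phases(ja, rep(1, nf), foot), "monotone")
})
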