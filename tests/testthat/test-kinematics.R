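template4 <- rbind(T1 = c(0, 0, 0), T2 = c(100, 0, 0),
                   T3 = c(0, 100, 0), T4 = c(0, 0, 100))

test_that("pose fit recovers identity and known transforms exactly", {
  fit <- fit_segment_pose(template4, template4)
  expect_true(fit$valid)
  expect_equal(fit$R, diag(3), tolerance = 1e-12)
  expect_equal(fit$t, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$residual, 0, tolerance = 1e-9)

  R90 <- rot_axis("Z", 90)
  obs <- sweep(template4 %*% t(R90), 2, c(100, 0, 0), "+")
  rownames(obs) <- rownames(template4)
  fit <- fit_segment_pose(obs, template4)
  expect_equal(fit$R, R90, tolerance = 1e-12)
  expect_equal(fit$t, c(100, 0, 0), tolerance = 1e-9)
  expect_equal(fit$residual, 0, tolerance = 1e-9)
})

test_that("pose fit matches the frame-construction oracle on exact 3-point data", {
  set.seed(21)
  for (i in 1:50) {
    P <- matrix(runif(9, -100, 100), 3, 3,
                dimnames = list(c("P1", "P2", "P3"), NULL))
    if (qr(scale(P, scale = FALSE))$rank < 2) next
    R <- random_rotation()
    tr <- runif(3, -500, 500)
    Q <- sweep(P %*% t(R), 2, tr, "+")
    rownames(Q) <- rownames(P)
    fit <- fit_segment_pose(Q, P)
    oracle <- rigid_from_three_points(P, Q)
    expect_equal(fit$R, oracle$R, tolerance = 1e-8)
    expect_equal(fit$t, oracle$t, tolerance = 1e-6)
    expect_lt(fit$residual, 1e-9)
    expect_rotation(fit$R)
  }
})

test_that("pose fit stays accurate under 1 mm marker noise", {
  # 12 coordinates minus 6 pose dof at sd 1 mm: E[residual RMS] ~ 1.2 mm,
  # so the mean over replicates sits well below 2 mm
  set.seed(8)
  resid <- ang <- numeric(50)
  for (i in 1:50) {
    obs <- template4 + matrix(rnorm(12, sd = 1), 4, 3)
    rownames(obs) <- rownames(template4)
    fit <- fit_segment_pose(obs, template4)
    resid[i] <- fit$residual
    ang[i] <- acos(pmin(1, (sum(diag(fit$R)) - 1) / 2)) * 180 / pi
  }
  expect_lt(mean(resid), 2)
  expect_lt(max(resid), 3)
  expect_lt(mean(ang), 1)
  expect_lt(max(ang), 3)
})

test_that("pose fit flags unusable frames and rejects collinear templates", {
  obs <- template4
  obs[3:4, ] <- NA_real_
  fit <- fit_segment_pose(obs, template4)
  expect_false(fit$valid)
  expect_true(all(is.na(fit$t)))

  line <- rbind(T1 = c(0, 0, 0), T2 = c(50, 0, 0), T3 = c(100, 0, 0))
  expect_error(fit_segment_pose(line, line), "collinear")
})

test_that("Cardan decompose/recompose is an identity for all six sequences", {
  seqs <- c("XYZ", "XZY", "YXZ", "YZX", "ZXY", "ZYX")
  expect_equal(cardan_decompose(diag(3))$angles, c(0, 0, 0))
  expect_equal(cardan_decompose(rot_axis("Y", 30), "YXZ")$angles,
               c(30, 0, 0), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:40) {
    a <- c(runif(1, -179, 179), runif(1, -85, 85), runif(1, -179, 179))
    for (sq in seqs) {
      R <- cardan_compose(a, sq)
      dec <- cardan_decompose(R, sq)
      expect_equal(cardan_compose(dec$angles, sq), R, tolerance = 1e-9)
      expect_equal(dec$angles, a, tolerance = 1e-9)
    }
  }
  expect_true(cardan_decompose(cardan_compose(c(0, 89.5, 0), "YXZ"),
                               "YXZ")$gimbal)
})

test_that("joint angles recover a prescribed relative rotation and unwrap", {
  model <- toy_model()
  nf <- 60
  fe <- seq(0, 30, length.out = nf)
  mk_pose <- function(R_list, org) {
    Rarr <- array(NA_real_, c(3, 3, nf))
    tt <- matrix(rep(org, each = nf), nf, 3)
    for (f in seq_len(nf)) Rarr[, , f] <- R_list[[f]]
    structure(list(segment = "x", R = Rarr, t = tt,
                   residual = rep(0, nf), valid = rep(TRUE, nf),
                   frame_rate = 200, n_frames = nf), class = "pose_series")
  }
  parent <- mk_pose(replicate(nf, diag(3), simplify = FALSE), c(0, 0, 0))
  child <- mk_pose(lapply(fe, function(a) rot_axis("Y", a)), c(0, 0, 200))
  ja <- compute_joint_angles(parent, child, "YXZ", joint = "hinge")
  expect_equal(ja$angles[, "fe"], fe, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(max(abs(ja$angles[, c("aa", "rot")])), 0, tolerance = 1e-9)
  expect_equal(compute_rom(ja$angles[, "fe"]), 30, tolerance = 1e-9)

  # angles crossing +-180 are unwrapped: no adjacent-frame jumps
  big <- seq(150, 210, length.out = nf)
  child2 <- mk_pose(lapply(big, function(a) rot_axis("Y", a)), c(0, 0, 200))
  ja2 <- compute_joint_angles(parent, child2, "YXZ")
  expect_lt(max(abs(diff(ja2$angles[, "fe"]))), 180)
  expect_equal(compute_rom(ja2$angles[, "fe"]), 60, tolerance = 1e-9)
})

test_that("ROM is max minus min and shift-invariant", {
  expect_equal(compute_rom(rep(12, 10)), 0)
  expect_equal(compute_rom(c(-10, 40, 119, 3)), 129)
  x <- rnorm(50)
  expect_equal(compute_rom(x + 1000), compute_rom(x))
  expect_error(compute_rom(numeric(0)), "empty")
})

test_that("angular velocity matches slopes and the sinusoid closed form", {
  expect_equal(max(abs(angular_velocity(rep(5, 10), 200)$omega)), 0)
  av <- angular_velocity(seq(0, 90, by = 10), 200)
  expect_equal(unique(round(av$omega, 6)), 2000)
  t <- seq(0, 1, by = 1 / 200)
  ang <- 90 * sin(2 * pi * 2 * t)
  pk <- angular_velocity(ang, 200)$peak
  expect_equal(pk, 2 * pi * 2 * 90, tolerance = 0.01)
  expect_error(angular_velocity(c(1, 2), 200), "3 frames")
})

test_that("peak deceleration interval tracks the post-peak decline", {
  t <- seq(0, 1, by = 1 / 200)
  ang <- 90 * sin(2 * pi * 1 * t)          # speed peaks at t = 0, 0.5, 1
  av <- angular_velocity(ang, 200)
  dec <- av$deceleration
  expect_gt(dec$drop_deg_s, 0.9 * av$peak) # falls essentially to zero
  expect_gt(dec$rate_deg_s2, 0)
  expect_gt(dec$end, dec$start)
})
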