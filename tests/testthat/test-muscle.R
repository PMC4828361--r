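test_that("muscle length is the polyline length through segment poses", {
  poses <- hinge_poses(rep(0, 3))
  static <- muscle_path("static", c("base", "base"),
                        rbind(c(0, 0, 0), c(60, 80, 0)))
  for (f in 1:3) expect_equal(muscle_length(static, poses, f), 100)

  # collinear via point adds nothing
  via <- muscle_path("via", c("base", "base", "base"),
                     rbind(c(0, 0, 0), c(30, 40, 0), c(60, 80, 0)))
  expect_equal(muscle_length(via, poses, 1), 100, tolerance = 1e-12)
})

test_that("hinge muscle length matches the law-of-cosines closed form", {
  theta <- seq(-60, 120, by = 5)
  poses <- hinge_poses(theta)
  lens <- vapply(seq_along(theta), function(f)
    muscle_length(hinge_muscle, poses, f), numeric(1))
  expect_equal(lens, hinge_length_closed_form(theta), tolerance = 1e-9)
  expect_lt(max(abs(lens - hinge_length_closed_form(theta))), 1e-6)
})

test_that("polyline length obeys the triangle inequality and rigid invariance", {
  set.seed(31)
  poses <- hinge_poses(runif(5, -90, 90))
  for (f in 1:5) {
    via <- muscle_path("v", c("base", "base", "arm"),
                       rbind(c(0, 0, 100), c(50, 30, 150), c(80, 0, 0)))
    # polyline through a via point >= straight path between the same ends
    direct <- muscle_length(hinge_muscle, poses, f)
    expect_gte(muscle_length(via, poses, f), direct - 1e-9)
  }
  # apply one global rigid transform to every pose: lengths unchanged
  G <- random_rotation(); g <- c(500, -200, 300)
  poses2 <- poses
  for (s in names(poses2)) for (f in 1:5) {
    poses2[[s]]$R[, , f] <- G %*% poses2[[s]]$R[, , f]
    poses2[[s]]$t[f, ] <- as.numeric(G %*% poses2[[s]]$t[f, ]) + g
  }
  for (f in 1:5)
    expect_equal(muscle_length(hinge_muscle, poses2, f),
                 muscle_length(hinge_muscle, poses, f), tolerance = 1e-9)
})

test_that("rest length normalisation is exact and scale-invariant", {
  model <- toy_model()
  np <- neutral_poses(model)
  m <- muscle_path("m", c("base", "arm"), rbind(c(0, 0, 100), c(80, 0, 0)))
  rest <- compute_rest_length(m, np)
  expect_equal(normalized_lengthening(rest, rest), 100)

  # scaling all local geometry by 1.1 scales rest length, not the ratio
  segs <- model$segments
  for (s in names(segs)) {
    segs[[s]]$markers <- segs[[s]]$markers * 1.1
    segs[[s]]$joint_offset <- segs[[s]]$joint_offset * 1.1
  }
  model2 <- skeleton_model(segs)
  m2 <- muscle_path("m", c("base", "arm"), m$points * 1.1)
  rest2 <- compute_rest_length(m2, neutral_poses(model2))
  expect_equal(rest2, rest * 1.1, tolerance = 1e-9)

  expect_equal(normalized_lengthening(135, 100), 135)
  expect_equal(normalized_lengthening(120, 100), 120)
  expect_error(normalized_lengthening(100, 0), "positive")
})

test_that("lengthening speed converts slopes to m/s and matches the sinusoid", {
  expect_equal(max(abs(lengthening_speed(rep(300, 10), 200)$speed)), 0)
  sp <- lengthening_speed(seq(100, by = 2, length.out = 20), 200)
  expect_equal(unique(round(sp$speed, 9)), 0.4)
  expect_equal(sp$max, 0.4)

  t <- seq(0, 1, by = 1 / 200)
  len <- 300 + 25 * sin(2 * pi * 2 * t)
  mx <- lengthening_speed(len, 200)$max
  expect_equal(mx, 2 * pi * 2 * 0.025, tolerance = 0.01)
  expect_error(lengthening_speed(c(1, 2), 200), "3 valid frames")
})

test_that("work pattern classification follows the sign of dL/dt", {
  fr <- 200
  expect_true(all(classify_work_pattern(seq(100, 200, by = 5), fr) ==
                    "lengthening"))
  expect_true(all(classify_work_pattern(rep(150, 10), fr) == "isometric"))
  tri <- c(seq(100, 200, by = 10), seq(190, 100, by = -10))
  pat <- classify_work_pattern(tri, fr)
  apex <- which.max(tri)
  expect_true(all(pat[2:(apex - 1)] == "lengthening"))
  expect_true(all(pat[(apex + 1):(length(tri) - 1)] == "shortening"))
  # dead band turns slow drift into isometric
  slow <- seq(100, 100.001, length.out = 10)
  expect_true(all(classify_work_pattern(slow, fr) == "isometric"))
})
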