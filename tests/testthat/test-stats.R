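test_that("describe returns mean and sample SD", {
  g <- describe(c(1, 2, 3))
  expect_equal(g$mean, 2)
  expect_equal(g$sd, 1)
  expect_equal(g$n, 3L)
  expect_equal(describe(rep(7, 5))$sd, 0)
  expect_error(describe(3), "at least 2")

  set.seed(123)
  x <- rnorm(1000, mean = 146.3, sd = 6.6)
  expect_lt(abs(describe(x)$mean - 146.3), 3 * 6.6 / sqrt(1000))
})

test_that("t_test_raw matches stats::t.test for both variants", {
  set.seed(77)
  for (i in 1:25) {
    a <- rnorm(sample(3:15, 1), mean = rnorm(1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:15, 1), mean = rnorm(1), sd = runif(1, 0.5, 3))
    for (v in c("pooled", "welch")) {
      mine <- t_test_raw(a, b, variant = v)
      ref <- stats::t.test(a, b, var.equal = (v == "pooled"))
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("t_test_raw handles hand-computed and degenerate cases", {
  r <- t_test_raw(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r$t), 3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)

  same <- t_test_raw(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  expect_error(t_test_raw(c(2, 2, 2), c(2, 2)), "undefined")
})

test_that("summary-based test is identical to the raw test", {
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(12, 0.5)
    for (v in c("pooled", "welch")) {
      raw <- t_test_raw(a, b, variant = v)
      smry <- t_test_from_summary(describe(a), describe(b), variant = v)
      expect_equal(smry$t, raw$t, tolerance = 1e-10)
      expect_equal(smry$df, raw$df, tolerance = 1e-10)
      expect_equal(smry$p, raw$p, tolerance = 1e-10)
    }
  }
})

test_that("p is symmetric under group swap while t changes sign", {
  g1 <- group_summary(10, 2, 7)
  g2 <- group_summary(12, 3, 13)
  r12 <- t_test_from_summary(g1, g2)
  r21 <- t_test_from_summary(g2, g1)
  expect_equal(r12$p, r21$p, tolerance = 1e-12)
  expect_equal(r12$t, -r21$t, tolerance = 1e-12)
})

test_that("published fan-vs-axe summaries reproduce the printed significance", {
  hip_fe <- t_test_from_summary(group_summary(146.3, 6.6, 7),
                                group_summary(162.2, 8.4, 13))
  expect_lt(hip_fe$p, 0.05)
  expect_true(hip_fe$significant)

  knee_fe <- t_test_from_summary(group_summary(108.9, 6.3, 7),
                                 group_summary(65.3, 4.7, 13))
  expect_lt(knee_fe$p, 0.01)

  eq <- t_test_from_summary(group_summary(5, 1, 10), group_summary(5, 1, 10))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})
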