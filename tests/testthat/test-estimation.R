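pts_sl <- to_probit_points(speak_listen_fixture())

test_that("endpoint estimator reproduces the worked-example advancement rate", {
  fit <- endpoint_estimate(pts_sl, span_scale = 12 / 11)
  expect_printed(fit$per_level$diff_z, c(0.6552, 0.4921, 0.8043, 0.5204), 4)
  expect_printed(fit$A, 0.6742, 4)
  expect_identical(fit$method, "endpoint")
  # default span scale rescales the observed midpoint span to a full year
  fit2 <- endpoint_estimate(pts_sl)
  expect_equal(fit2$span_scale, 1 / (0.9575342 - 0.0410959), tolerance = 1e-5)
})

test_that("endpoint estimator handles degenerate and partial inputs", {
  # two intervals, one level, equal z -> A = 0
  pts <- ttgrae:::new_probit_points(data.frame(
    interval = c("a", "b"), t_B = c(0.1, 0.9), level = "L1",
    level_index = 1L, p = c(0.2, 0.2), z = probit_upper(c(0.2, 0.2)), n = 50))
  expect_equal(endpoint_estimate(pts)$A, 0)
  # a level missing an endpoint interval is skipped with a warning
  part <- rbind(as.data.frame(pts),
                data.frame(interval = "a", t_B = 0.1, level = "L2",
                           level_index = 2L, p = 0.1,
                           z = probit_upper(0.1), n = 50))
  expect_warning(fit <- endpoint_estimate(ttgrae:::new_probit_points(part)),
                 "missing an endpoint")
  expect_equal(nrow(fit$per_level), 1)
  expect_error(endpoint_estimate(ttgrae:::new_probit_points(
    data.frame(interval = "a", t_B = 0.5, level = "L1", level_index = 1L,
               p = 0.2, z = probit_upper(0.2), n = 10))),
    "share one birthtime")
})

test_that("per-level regression reproduces the worked-example slopes", {
  fit <- per_level_regression(pts_sl)
  expect_printed(fit$per_level$slope, c(0.6716, 0.5965, 0.7441, 0.5583), 4)
  expect_printed(fit$A, 0.6426, 4)
  # identical z at all birthtimes -> slope 0
  flat <- ttgrae:::new_probit_points(data.frame(
    interval = letters[1:4], t_B = c(0.1, 0.4, 0.6, 0.9), level = "L1",
    level_index = 1L, p = 0.3, z = probit_upper(rep(0.3, 4)), n = 100))
  expect_equal(per_level_regression(flat)$A, 0, tolerance = 1e-12)
})

test_that("stacked regression reproduces the printed coefficients for both studies", {
  fit <- stacked_regression(pts_sl)
  expect_printed(fit$A, 0.643, 3)
  expect_printed(fit$t_A, 13.08, 2)
  expect_printed(fit$R2, 0.995, 3)
  expect_equal(fit$df, 43)
  expect_lt(fit$p_A, 1e-15)
  expect_length(fit$level_offsets, 3)

  soccer <- epl_academy_points()
  f2 <- stacked_regression(soccer)
  expect_printed(f2$A, 0.689, 3)
  expect_printed(f2$C, 2.429, 3)
  expect_printed(f2$R2, 0.9987, 4)
  expect_printed(f2$t_A, 27.69, 2)
  expect_equal(f2$df, 1)
  expect_length(f2$level_offsets, 0)
})

test_that("all three estimators agree on noiseless model data", {
  t_mid <- midpoints(month_grid("Sep"))
  pts <- model_points(A = 0.8, criteria = c(0.5, 1.1), t_mid = t_mid)
  span <- 1 / (max(t_mid) - min(t_mid))
  a1 <- endpoint_estimate(pts, span_scale = span)$A
  a2 <- per_level_regression(pts)$A
  a3 <- stacked_regression(pts)$A
  expect_equal(a1, 0.8, tolerance = 1e-8)
  expect_equal(a2, 0.8, tolerance = 1e-8)
  expect_equal(a3, 0.8, tolerance = 1e-8)
  # stacked fit recovers C and the level offset exactly
  fit <- stacked_regression(pts)
  expect_equal(fit$C, 0.5, tolerance = 1e-10)
  expect_equal(unname(fit$level_offsets), 0.6, tolerance = 1e-10)
})

test_that("with a balanced design the stacked slope equals the mean per-level slope", {
  # noisy but balanced: same t_B design at every level
  set.seed(11)
  t_mid <- midpoints(month_grid("Sep"))
  pts <- model_points(A = 0.7, criteria = c(0.2, 0.9, 1.4), t_mid = t_mid)
  pts$z <- pts$z + rnorm(nrow(pts), sd = 0.05)
  pts$p <- pnorm(pts$z, lower.tail = FALSE)
  expect_equal(stacked_regression(pts)$A, per_level_regression(pts)$A,
               tolerance = 1e-10)
})

test_that("quadratic and interaction model comparisons match the printed F statistics", {
  q <- compare_models(pts_sl, "quadratic")
  expect_printed(q$F, 2.32, 2)
  expect_equal(c(q$df1, q$df2), c(1, 42))
  expect_gt(q$p, 0.1)
  i <- compare_models(pts_sl, "interaction")
  expect_lt(i$F, 1)
  expect_equal(c(i$df1, i$df2), c(3, 40))
  # agreement with the anova() F as an independent route
  d <- ttgrae:::.stacked_data(pts_sl)
  a <- anova(lm(z ~ t_B + level, d), lm(z ~ t_B + level + I(t_B^2), d))
  expect_equal(q$F, a$F[2], tolerance = 1e-10)
})

test_that("model comparison is exact-fit safe and df-checked", {
  pts <- model_points(A = 0.8, criteria = c(0.5, 1.1),
                      t_mid = midpoints(month_grid("Sep")))
  expect_equal(compare_models(pts, "quadratic")$F, 0)
  expect_equal(compare_models(pts, "interaction")$F, 0)
  # three points, one level: adding a quadratic leaves no residual df
  expect_error(compare_models(epl_academy_points(), "quadratic"),
               "degrees of freedom")
  expect_error(compare_models(epl_academy_points(), "interaction"),
               "two severity levels")
})

test_that("a genuinely quadratic advancement curve is detected", {
  # z(t) = C + A t + 2 t^2 with small noise; the quadratic comparison
  # should reject at alpha = 0.01 nearly always
  t_mid <- midpoints(month_grid("Sep"))
  n_rep <- 500
  rej <- ttgrae:::with_seed(20170420, {
    mean(vapply(seq_len(n_rep), function(r) {
      z <- 0.5 + 0.8 * t_mid + 2 * t_mid^2 + rnorm(12, sd = 0.05)
      pts <- ttgrae:::new_probit_points(data.frame(
        interval = month_labels, t_B = t_mid, level = "L1", level_index = 1L,
        p = pnorm(z, lower.tail = FALSE), z = z, n = 450))
      compare_models(pts, "quadratic")$p < 0.01
    }, logical(1)))
  })
  expect_gt(rej, 0.95)
})

test_that("under a truly linear model the quadratic test rejects at its nominal rate", {
  t_mid <- midpoints(month_grid("Sep"))
  n_rep <- 1000
  rej <- ttgrae:::with_seed(99, {
    mean(vapply(seq_len(n_rep), function(r) {
      z <- 0.5 + 0.8 * t_mid + rnorm(12, sd = 0.1)
      pts <- ttgrae:::new_probit_points(data.frame(
        interval = month_labels, t_B = t_mid, level = "L1", level_index = 1L,
        p = pnorm(z, lower.tail = FALSE), z = z, n = 450))
      compare_models(pts, "quadratic")$p < 0.05
    }, logical(1)))
  })
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})
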