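test_that("left/right knees of one subject are averaged before analysis", {
  df <- data.frame(subject = c("a", "a", "b"), side = c("left", "right", "left"),
                   voi_name = "tibia.S1.medial", bmd = c(10, 20, 7))
  out <- average_paired_sides(df)
  expect_equal(nrow(out), 2L)
  expect_equal(out$bmd[out$subject == "a"], 15)
  expect_equal(out$bmd[out$subject == "b"], 7)   # singleton passes through

  dup <- rbind(df, df[1, ])
  expect_error(average_paired_sides(dup), "duplicate")

  # a 57-knee / 32-subject roster collapses to 32 rows
  set.seed(61)
  subjects <- sprintf("s%02d", 1:32)
  paired <- sample(subjects, 25)   # 25 subjects with both knees = 57 knees
  roster <- data.frame(
    subject = c(subjects, paired),
    side = c(rep("left", 32), rep("right", 25)),
    voi_name = "femur.S2.medial",
    value = stats::rnorm(57, 200, 40))
  expect_equal(nrow(roster), 57L)
  out2 <- average_paired_sides(roster)
  expect_equal(nrow(out2), 32L)
  for (s in paired)
    expect_equal(out2$value[out2$subject == s],
                 mean(roster$value[roster$subject == s]))
})

test_that("linear regression agrees with the closed-form normal equations", {
  x <- 1:10
  r <- linear_regression(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)

  rc <- linear_regression(x, rep(5, 10))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  expect_equal(rc$p_value, 1)

  set.seed(62)
  for (rep in 1:10) {
    xr <- stats::rnorm(15, 100, 20)
    yr <- 0.7 * xr + stats::rnorm(15, 0, 10)
    got <- linear_regression(xr, yr)
    orc <- oracle_ols(xr, yr)
    expect_equal(got$slope, orc$slope, tolerance = 1e-10)
    expect_equal(got$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, orc$r_squared, tolerance = 1e-10)
    expect_equal(got$p_value, orc$p_value, tolerance = 1e-10)
  }
  expect_error(linear_regression(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(linear_regression(1:2, 1:2), "3 points")
})

test_that("Bland-Altman statistics follow the declared SD convention", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3), reference_mean = 2)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa, 0)
  expect_equal(ba0$pct_err, 0)

  # d = {-1, +1}: population SD = 1, LOA = 1.96
  ba <- bland_altman(c(9, 11), c(10, 10), reference_mean = 10)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa, 1.96)
  expect_equal(ba$pct_err, 0.196)
  expect_true(all(ba$within_loa))

  # outlier flagging on a constructed series
  a <- c(10, 10, 10, 10, 25)
  b <- c(10, 10.5, 9.5, 10, 10)
  ba2 <- bland_altman(a, b, reference_mean = 10)
  d <- a - b
  expect_identical(unname(ba2$within_loa),
                   d >= ba2$mean_diff - ba2$loa - 1e-12 &
                     d <= ba2$mean_diff + ba2$loa + 1e-12)
  expect_error(bland_altman(1:3, 1:4, 1), "equal length")
})

test_that("resolution-dependence ratios and their two-stage summary", {
  expect_equal(resolution_dependence(3, 3)$d, 1)
  expect_equal(resolution_dependence(2, 4)$d, 0.5)
  expect_error(resolution_dependence(2, 0), "undefined")

  ones <- expand.grid(case = 1:3, voi_name = paste0("tibia.S", 1:3, ".medial"))
  ones$parameter <- "entropy"
  ones$d <- 1
  s1 <- d_summary(ones)
  expect_equal(s1$mean_d, 1)
  expect_equal(s1$sd_d, 0)

  two <- data.frame(case = c(1, 2), voi_name = "femur.S1.lateral",
                    parameter = "entropy", d = c(0.8, 1.2))
  expect_equal(d_summary(two)$mean_d, 1.0)

  # unbalanced VOI counts: two-stage mean computed by hand
  ub <- data.frame(case = c(1, 1, 1, 2, 3, 3),
                   voi_name = "femur.S2.medial", parameter = "anisotropy",
                   d = c(0.9, 1.0, 1.1, 1.4, 0.6, 0.8))
  s2 <- d_summary(ub)
  hand <- mean(c(mean(c(0.9, 1.0, 1.1)), 1.4, mean(c(0.6, 0.8))))
  expect_equal(s2$mean_d, hand)
  expect_equal(s2$n_cases, 3L)

  cort <- data.frame(case = 1, voi_name = "femur.cortical.medial",
                     parameter = "entropy", d = 1)
  expect_error(d_summary(cort), "cortical")
})

test_that("group comparison reports t, normality and variance diagnostics", {
  set.seed(63)
  x <- stats::rnorm(20)
  gc0 <- group_comparison(x, x)
  expect_equal(unname(gc0$t_statistic), 0)
  expect_equal(gc0$t_p, 1)
  expect_identical(gc0$alpha, 0.05)

  y <- stats::rnorm(25, 0.2, 2)
  gc1 <- group_comparison(x, y)
  expect_equal(gc1$t_p, stats::t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(unname(gc1$normal_p["model"]), stats::shapiro.test(x)$p.value)

  # Levene/Brown-Forsythe against a closed-form computation
  lv <- trabtex:::levene_test(x, y)
  zx <- abs(x - stats::median(x)); zy <- abs(y - stats::median(y))
  grp <- factor(rep(1:2, c(length(zx), length(zy))))
  aov_f <- summary(stats::aov(c(zx, zy) ~ grp))[[1]]$`F value`[1]
  expect_equal(lv$statistic, aov_f, tolerance = 1e-10)
  expect_error(group_comparison(1:2, 1:5), "at least 3")

  # a clear shift is detected (2 SD effect, n = 40)
  set.seed(64)
  hits <- mean(replicate(50, {
    a <- stats::rnorm(40); b <- stats::rnorm(40, 2)
    group_comparison(a, b)$t_p < 0.05
  }))
  expect_gt(hits, 0.95)
})
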