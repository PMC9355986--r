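make_pairs <- function(x, y, bee = "bee01") {
  data.frame(bee_id = bee, start_sample = seq_along(x) * 256 - 256,
             peak_fx_mn = y, peak_fy_mn = y / 2, peak_fz_mn = y / 1.5,
             peak_displacement_um = x, peak_velocity_mm_s = x,
             peak_acceleration_m_s2 = x, dominant_frequency_hz = 130)
}

test_that("subdividing one interval yields four unique 256-sample pairs", {
  rec <- sine_recording(n = 1024, freq = 130)
  an <- analyze_recording(rec)
  pairs <- subdivide_for_regression(an)
  expect_equal(nrow(pairs), 4)
  expect_equal(pairs$start_sample, c(0, 256, 512, 768))
})

test_that("sinusoid subinterval peaks match the full-interval peak within 2%", {
  # 130 Hz: each 256-sample subinterval holds >= 3 full periods
  rec <- sine_recording(n = 4096, freq = 130)
  an <- analyze_recording(rec)
  pairs <- subdivide_for_regression(an)
  full_peak <- an$metrics$peak_fx_mn[2]
  inner <- pairs[pairs$start_sample >= 512 &
                   pairs$start_sample < 3072, "peak_fx_mn"]
  expect_true(all(abs(inner - full_peak) / full_peak < 0.02))
})

test_that("overlapping parent intervals contribute each subinterval once", {
  rec <- sine_recording(n = 2048, freq = 130)
  an <- analyze_recording(rec)
  pairs <- subdivide_for_regression(an)
  expect_equal(anyDuplicated(pairs$start_sample), 0L)
  expect_equal(nrow(pairs), 8)   # 3 overlapping windows span 2048 samples
  expect_error(subdivide_for_regression(an, n_sub = 3), "divide")
})

test_that("OLS agrees with the normal-equation solution to 1e-10", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    x <- rnorm(n, 10, 4)
    y <- 2.5 * x + rnorm(n)
    f <- fit_force_kinematics(make_pairs(x, y), "velocity", "total")
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_rel(f$intercept, beta[1], 1e-10)
    expect_rel(f$slope, beta[2], 1e-10)
  }
})

test_that("exact linear data is fit exactly", {
  x <- c(1, 2, 3, 4, 5)
  # noise-free input: lm warns about the perfect fit, which is the point here
  f <- suppressWarnings(
    fit_force_kinematics(make_pairs(x, 2 * x + 1), "velocity", "total"))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$pearson_r, 1, tolerance = 1e-12)
})

test_that("degenerate fits are refused", {
  expect_error(fit_force_kinematics(make_pairs(rep(3, 10), rnorm(10)),
                                    "velocity", "total"), "degenerate")
  expect_error(fit_force_kinematics(make_pairs(1:2, 1:2), "velocity",
                                    "total"), ">= 3")
})

test_that("Pearson r is scale- and shift-invariant; null slope CI covers 0", {
  set.seed(9)
  x <- rnorm(50, 100, 20)
  y <- 0.8 * x + rnorm(50, 0, 10)
  r1 <- fit_force_kinematics(make_pairs(x, y), "velocity", "total")$pearson_r
  r2 <- fit_force_kinematics(make_pairs(3 * x - 40, 0.1 * y + 7),
                             "velocity", "total")$pearson_r
  expect_equal(r1, r2, tolerance = 1e-12)

  cover <- 0
  for (i in 1:40) {
    set.seed(1000 + i)
    xn <- rnorm(30, 100, 15)
    yn <- rnorm(30, 150, 30)   # independent of xn
    f <- fit_force_kinematics(make_pairs(xn, yn), "velocity", "total")
    cover <- cover + (f$slope_ci_lo <= 0 && 0 <= f$slope_ci_hi)
  }
  expect_gte(cover / 40, 0.85)
})

test_that("mixed ANOVA needs a real random-effects design", {
  d <- data.frame(bee_id = "b1", post = "plastic", value = rnorm(10))
  expect_error(mixed_anova(d, "post"), "single bee")
  d2 <- data.frame(bee_id = rep(c("b1", "b2"), each = 10),
                   post = rep(c("plastic", "carbon"), each = 10),
                   value = rnorm(20))
  expect_error(mixed_anova(d2, "post"), "2 bees per post")
})

test_that("a large Fx offset is detected as a direction effect (p < 0.001)", {
  set.seed(14)
  bees <- sprintf("bee%02d", 1:10)
  d <- expand.grid(bee_id = bees, interval = 1:8,
                   direction = c("x", "y", "z"))
  bee_eff <- rnorm(10, 0, 5)
  names(bee_eff) <- bees
  d$value <- 70 + bee_eff[d$bee_id] + rnorm(nrow(d), 0, 8) +
    ifelse(d$direction == "x", 100, 0)
  an <- mixed_anova(d, "direction", log_transform = "never")
  expect_lt(an$terms$p[an$terms$term == "direction"], 0.001)

  # distribution-free cross-check: within-bee permutation of direction labels
  f_obs <- an$terms$F[an$terms$term == "direction"]
  set.seed(15)
  f_perm <- replicate(30, {
    dp <- d
    for (b in bees) {
      i <- which(dp$bee_id == b)
      dp$direction[i] <- sample(dp$direction[i])
    }
    mixed_anova(dp, "direction", log_transform = "never")$terms$F[1]
  })
  expect_true(all(f_perm < f_obs))
})

test_that("log transform is applied when residuals are non-normal", {
  set.seed(16)
  d <- data.frame(bee_id = rep(sprintf("b%d", 1:6), each = 30),
                  post = rep(c("plastic", "carbon"), each = 90))
  d$value <- exp(rnorm(nrow(d), 3, 0.8))   # strongly right-skewed
  an <- mixed_anova(d, "post", log_transform = "auto")
  expect_true(an$transform_applied)
  an2 <- mixed_anova(d, "post", log_transform = "never")
  expect_false(an2$transform_applied)
})

test_that("population summaries collapse correctly across bees", {
  base <- data.frame(
    bee_id = rep(sprintf("bee%02d", 1:10), each = 3),
    interval_index = rep(0:2, 10), start_sample = rep(c(0L, 512L, 1024L), 10),
    qc_pass = TRUE, qc_reasons = "",
    dominant_frequency_hz = 130, peak_fx_mn = 170, peak_fy_mn = 67,
    peak_fz_mn = 115, peak_displacement_um = 32, peak_velocity_mm_s = 98,
    peak_acceleration_m_s2 = 91)
  s <- summarize_population(base)
  expect_equal(attr(s, "n_bees"), 10)
  expect_true(all(s$sd == 0))
  expect_equal(s$q1, s$q3)
  expect_equal(s$q1, s$mean)
  expect_equal(s$mean[s$quantity == "fx_mn"], 170)

  # permutation invariance
  perm <- base[sample(nrow(base)), ]
  perm <- perm[order(perm$bee_id, perm$interval_index), ]
  expect_equal(summarize_population(perm), s)
})

test_that("bee_means aggregation shields against unequal interval counts", {
  set.seed(20)
  m <- data.frame(
    bee_id = rep(c("a", "b"), each = 4),
    interval_index = rep(0:3, 2), start_sample = rep(512L * (0:3), 2),
    qc_pass = TRUE, qc_reasons = "",
    dominant_frequency_hz = rep(c(120, 150), each = 4),
    peak_fx_mn = rep(c(150, 200), each = 4), peak_fy_mn = 60,
    peak_fz_mn = 100, peak_displacement_um = 30,
    peak_velocity_mm_s = rep(c(80, 120), each = 4),
    peak_acceleration_m_s2 = 90)
  dup <- m[m$bee_id == "a", ]
  dup$interval_index <- dup$interval_index + 4L
  dup$start_sample <- dup$start_sample + 2048L
  m2 <- rbind(m, dup)
  m2 <- m2[order(m2$bee_id, m2$interval_index), ]

  s1 <- summarize_population(m, "bee_means")
  s2 <- summarize_population(m2, "bee_means")
  expect_equal(s1$mean, s2$mean)

  p1 <- summarize_population(m, "pooled")
  p2 <- summarize_population(m2, "pooled")
  expect_false(isTRUE(all.equal(p1$mean, p2$mean)))
})

test_that("bees without valid intervals are excluded with a warning", {
  m <- data.frame(
    bee_id = rep(c("a", "b"), each = 2),
    interval_index = rep(0:1, 2), start_sample = rep(c(0L, 512L), 2),
    qc_pass = c(TRUE, TRUE, FALSE, FALSE),
    qc_reasons = c("", "", "low_force", "low_force"),
    dominant_frequency_hz = 130, peak_fx_mn = 170, peak_fy_mn = 67,
    peak_fz_mn = 115, peak_displacement_um = 32, peak_velocity_mm_s = 98,
    peak_acceleration_m_s2 = 91)
  expect_warning(s <- summarize_population(m), "no QC-passing")
  expect_equal(attr(s, "n_bees"), 1)
})
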