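test_that("fit_line does OLS with the degenerate-R^2 conventions", {
  f <- fit_line(c(0, 1, 2), c(0, 1, 2))
  expect_equal(c(f$slope, f$intercept, f$r_squared), c(1, 0, 1))

  # noiseless control rising points: coefficients known in closed form
  p <- control_labelling()
  tt <- c(0.5, 2.5, 4.5)
  f <- fit_line(tt, expected_li(p, tt))
  expect_equal(f$slope, 0.11 / 10.5, tolerance = 1e-12)     # GF/Tc
  expect_equal(f$intercept, 0.11 * 5 / 10.5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  # constant series: zero slope, R^2 defined as 1
  f <- fit_line(c(0, 1, 2), c(0.1, 0.1, 0.1))
  expect_equal(c(f$slope, f$intercept, f$r_squared), c(0, 0.1, 1))

  expect_error(fit_line(1, 0.5), "insufficient")
  expect_error(fit_line(c(2, 2, 2), c(0.1, 0.2, 0.3)), "times equal")
})

test_that("fit_line agrees with lm() on noisy data (oracle)", {
  set.seed(21)
  for (i in 1:20) {
    t <- sort(runif(8, 0, 12))
    y <- 0.05 + 0.01 * t + rnorm(8, sd = 0.01)
    f <- fit_line(t, y)
    m <- lm(y ~ t)
    expect_equal(f$slope, unname(coef(m)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(m)[1]), tolerance = 1e-10)
    expect_equal(f$r_squared, summary(m)$r.squared, tolerance = 1e-10)
    expect_equal(f$slope_se, summary(m)$coefficients[2, 2],
                 tolerance = 1e-10)
  }
})

test_that("detect_plateau segments rise from plateau", {
  # noiseless control: unique zero-SSE split at 3 rising / 3 plateau
  seg <- detect_plateau(noiseless_series(control_labelling()))
  expect_equal(seg$rising, 1:3)
  expect_equal(seg$plateau, 4:6)

  # strictly rising line: every admissible plateau is itself rising
  lin <- data.frame(time_h = exp_times(),
                    li = 0.2774 + 0.006917 * exp_times())
  expect_null(detect_plateau(lin))

  # constant series: tie broken toward the larger plateau
  const <- data.frame(time_h = exp_times(), li = rep(0.1, 6))
  seg <- detect_plateau(const)
  expect_equal(seg$rising, 1:2)
  expect_equal(seg$plateau, 3:6)

  expect_error(detect_plateau(const[1:2, ]), "insufficient")
})

test_that("fit_cumulative recovers the control parameters from a plateau", {
  fit <- fit_cumulative(noiseless_series(control_labelling()))
  expect_s3_class(fit, "cumulative_fit")
  expect_equal(fit$mode, "plateau_reached")
  expect_equal(fit$gf, 0.11, tolerance = 1e-9)
  expect_equal(fit$tc, 10.5, tolerance = 1e-9)
  expect_equal(fit$ts, 5.0, tolerance = 1e-9)
  expect_equal(fit$t_plateau, 5.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # internal identities
  expect_equal(fit$tc, fit$lim / fit$slope, tolerance = 1e-12)
  expect_equal(fit$ts, fit$li0 / fit$slope, tolerance = 1e-12)
  expect_equal(fit$tc - fit$ts, fit$t_plateau, tolerance = 1e-9)
})

test_that("fit_cumulative falls back to a minimum estimate on rising data", {
  lin <- data.frame(time_h = exp_times(),
                    li = 0.2774 + 0.006917 * exp_times())
  fit <- fit_cumulative(lin)
  expect_equal(fit$mode, "minimum_estimate")
  expect_equal(fit$t_plateau, 10.5)
  expect_equal(fit$lim, 0.2774 + 0.006917 * 10.5, tolerance = 1e-9)
  expect_equal(fit$lim, 0.3500, tolerance = 1e-4)
  expect_equal(fit$tc, 50.6, tolerance = 0.1 / 50.6)
  expect_equal(fit$n_plateau, 0L)
})

test_that("fit_cumulative rejects degenerate series", {
  const <- data.frame(time_h = exp_times(), li = rep(0.1, 6))
  expect_error(fit_cumulative(const), "no estimate")
  falling <- data.frame(time_h = exp_times(),
                        li = 0.3 - 0.01 * exp_times())
  expect_error(fit_cumulative(falling), "no estimate")
  expect_error(fit_cumulative(const[1:2, ]), "insufficient")
  bad <- data.frame(time_h = exp_times(), li = c(0.1, 0.2, 0.3, 1.4, 1.4, 1.4))
  expect_error(fit_cumulative(bad), "\\[0, 1\\]")
})

test_that("noiseless forward-model data is recovered exactly (property)", {
  set.seed(22)
  for (i in 1:50) {
    p <- random_params_in_window()
    fit <- fit_cumulative(noiseless_series(p))
    expect_equal(fit$mode, "plateau_reached")
    expect_equal(fit$tc, p$tc, tolerance = 1e-6)
    expect_equal(fit$ts, p$ts, tolerance = 1e-6)
    expect_equal(fit$gf, p$gf, tolerance = 1e-6)
  }
})

test_that("estimates are invariant to time-unit rescaling", {
  set.seed(23)
  li <- expected_li(control_labelling(), exp_times()) +
    rnorm(6, sd = 0.004)
  li <- pmin(pmax(li, 0), 1)
  for (c_scale in c(60, 1 / 24)) {  # hours -> minutes, hours -> days
    f1 <- fit_cumulative(data.frame(time_h = exp_times(), li = li))
    f2 <- fit_cumulative(data.frame(time_h = c_scale * exp_times(), li = li))
    expect_equal(f2$tc, c_scale * f1$tc, tolerance = 1e-9)
    expect_equal(f2$ts, c_scale * f1$ts, tolerance = 1e-9)
    expect_equal(f2$gf, f1$gf, tolerance = 1e-9)
    expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
  }
})

test_that("minimum-estimate Tc is non-decreasing in the last time", {
  for (li0 in c(0.1, 0.2774)) {
    slope <- 0.006917
    tcs <- sapply(c(6.5, 8.5, 10.5, 12.5), function(t_last) {
      tt <- seq(0.5, t_last, by = 2)
      fit_cumulative(data.frame(time_h = tt, li = li0 + slope * tt))$tc
    })
    expect_true(all(diff(tcs) >= -1e-12))
  }
})
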