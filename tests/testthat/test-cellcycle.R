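test_that("expected_li follows the linear-rise-then-plateau closed form", {
  ph <- control_phases()  # T_C = 76.6, T_S = 13.5
  expect_equal(expected_li(ph, 1, 0), 13.5 / 76.6)
  expect_equal(expected_li(ph, 1, 63.1), 1.0)          # plateau at t_c - t_s
  expect_equal(expected_li(ph, 0.5, 0), 0.5 * 13.5 / 76.6)  # linear in g
  # continuity and monotonicity across the plateau
  t <- seq(0, 100, by = 0.5)
  li <- expected_li(ph, 0.8, t)
  expect_true(all(diff(li) >= 0))
  expect_true(all(li <= 0.8 + 1e-15))
  expect_equal(max(li), 0.8)
})

test_that("phase_durations rejects invalid phase combinations", {
  expect_error(phase_durations(-1, 13.5), "durations")
  expect_error(phase_durations(10, 0), "t_s")
  expect_silent(phase_durations(0, 0.1))
})

test_that("fit_labeling_curve recovers an exact line and derived durations", {
  t <- c(3, 6, 12, 18, 24)
  d <- data.frame(time_h = t, li = 0.1 + 0.01 * t)
  fit <- fit_labeling_curve(d, g = 1)
  expect_equal(unname(coef(fit)), c(0.01, 0.1), tolerance = 1e-12)
  expect_equal(fit$t_c, 100, tolerance = 1e-10)
  expect_equal(fit$t_s, 10, tolerance = 1e-10)
  expect_false(fit$plateau_reached)
  # agrees with an independent OLS oracle on noise-free data
  orc <- ols_line_oracle(t, d$li)
  expect_equal(fit$m, unname(orc["m"]), tolerance = 1e-10)
  expect_equal(fit$y0, unname(orc["y0"]), tolerance = 1e-10)
})

test_that("round-trip through the closed form recovers the study durations", {
  for (ph in list(control_phases(), cko_phases())) {
    t <- c(3, 6, 9, 12, 18, 24)
    d <- data.frame(time_h = t, li = expected_li(ph, 1, t))
    fit <- fit_labeling_curve(d, g = 1)
    expect_equal(fit$t_c, ph$t_c, tolerance = 1e-9)
    expect_equal(fit$t_s, ph$t_s, tolerance = 1e-9)
  }
})

test_that("degenerate designs and plateau-only data raise errors", {
  expect_error(
    fit_labeling_curve(data.frame(time_h = c(5, 5), li = c(0.1, 0.2)), g = 1),
    "distinct")
  expect_error(
    fit_labeling_curve(data.frame(time_h = c(70, 80), li = c(1, 1)), g = 1),
    "plateau")
  expect_error(
    fit_labeling_curve(data.frame(time_h = c(3, 6), li = c(0.3, 0.2)), g = 1),
    "non-identifiable")
})

test_that("auto growth fraction needs a sampled plateau, else defaults to 1", {
  ph <- phase_durations(t_g1 = 20, t_s = 5, t_g2 = 1)  # t_c = 26
  t <- c(2, 4, 8, 30, 40)  # last two sit on the plateau
  d <- data.frame(time_h = t, li = expected_li(ph, 0.6, t))
  fit <- fit_labeling_curve(d, g = "auto")
  expect_equal(fit$g, 0.6, tolerance = 1e-12)
  expect_equal(fit$t_c, 26, tolerance = 1e-9)
  expect_equal(sort(fit$excluded), c(4L, 5L))
  expect_true(fit$plateau_reached)
  # no plateau sampled: g falls back to 1
  d2 <- data.frame(time_h = c(2, 4, 8), li = expected_li(ph, 0.6, c(2, 4, 8)))
  fit2 <- fit_labeling_curve(d2, g = "auto")
  expect_equal(fit2$g, 1)
})

test_that("closed-form/fit equivalence holds across random valid conditions", {
  set.seed(401)
  for (i in 1:25) {
    ph <- phase_durations(runif(1, 5, 200), runif(1, 2, 30),
                          runif(1, 0, 5), runif(1, 0, 2))
    g <- runif(1, 0.3, 1)
    t_max <- 0.9 * (ph$t_c - ph$t_s)
    t <- seq(t_max / 6, t_max, length.out = 6)
    d <- data.frame(time_h = t, li = expected_li(ph, g, t))
    fit <- fit_labeling_curve(d, g = g)
    expect_equal(fit$m, g / ph$t_c, tolerance = 1e-9)
    expect_equal(fit$y0, g * ph$t_s / ph$t_c, tolerance = 1e-9)
  }
})

test_that("estimate_tc_ts inverts slope and intercept algebraically", {
  expect_equal(estimate_tc_ts(0.5, 0, 1), c(t_c = 2, t_s = 0))
  cko <- estimate_tc_ts(0.005587, 0.09330, 1)
  expect_equal(unname(cko["t_c"]), 179.0, tolerance = 5e-4)
  expect_equal(unname(cko["t_s"]), 16.7, tolerance = 5e-3)
  ctl <- estimate_tc_ts(0.013055, 0.17624, 1)
  expect_equal(unname(ctl["t_c"]), 76.6, tolerance = 5e-4)
  expect_equal(unname(ctl["t_s"]), 13.5, tolerance = 5e-3)
  expect_error(estimate_tc_ts(-0.1, 0.1, 1), "m")
  expect_error(estimate_tc_ts(0.1, 1.1, 1), "y0")
})

test_that("arithmetic mixture correction matches hand arithmetic", {
  expect_equal(correct_mixture_arithmetic(179, 0.8, 77), (179 - 77 * 0.2) / 0.8)
  expect_equal(correct_mixture_arithmetic(150, 1.0, 77), 150)  # identity
  expect_equal(correct_mixture_arithmetic(100, 0.5, 60), 140)  # (100 - 30)/0.5
  expect_error(correct_mixture_arithmetic(10, 0.1, 150), "inconsistent")
  expect_error(correct_mixture_arithmetic(179, 0, 77), "f_rec")
})

test_that("harmonic (slope-consistent) mixture correction inverts the mixture slope", {
  expect_equal(correct_mixture_harmonic(1 / 179, 1.0, 77, 1), 179)  # identity
  # forward slope of an 80/20 mixture with component cycle times 204.5 / 77 h
  m_mix <- 0.8 / 204.5 + 0.2 / 77
  expect_equal(correct_mixture_harmonic(m_mix, 0.8, 77, 1), 204.5,
               tolerance = 1e-12)
  expect_error(correct_mixture_harmonic(0.002, 0.8, 77, 1), "inconsistent")
})

test_that("both mixture corrections are the identity at full recombination", {
  set.seed(402)
  for (i in 1:10) {
    x <- runif(1, 10, 300); y <- runif(1, 10, 300); g <- runif(1, 0.2, 1)
    expect_equal(correct_mixture_arithmetic(x, 1, y), x)
    expect_equal(correct_mixture_harmonic(g / x, 1, y, g), x, tolerance = 1e-12)
  }
})

test_that("G2 estimator reproduces the labeled-mitoses reconstruction", {
  g2_ctl <- estimate_g2(4, 0.165, 13.5)
  expect_equal(as.numeric(g2_ctl), 1.7725)
  expect_equal(format_duration(as.numeric(g2_ctl)), "1.8")
  g2_cko <- estimate_g2(4, 0.060, 16.7)
  expect_equal(as.numeric(g2_cko), 2.998)
  expect_equal(format_duration(as.numeric(g2_cko)), "3.0")
  # no labeled mitoses yet: chase time is only a lower bound on G2
  g2_lb <- estimate_g2(4, 0, 13.5)
  expect_equal(as.numeric(g2_lb), 4)
  expect_true(attr(g2_lb, "lower_bound"))
  # over-long chase clips at zero with a warning flag
  expect_warning(g2_clip <- estimate_g2(1, 0.9, 13.5), "clipped")
  expect_equal(as.numeric(g2_clip), 0)
  expect_true(attr(g2_clip, "clipped"))
})

test_that("G1 by subtraction matches the study arithmetic", {
  expect_equal(estimate_g1(179, 16.7, 3), 159.3)
  expect_equal(estimate_g1(76.6, 13.5, 1.8), 61.3)
  expect_equal(estimate_g1(10, 10, 0, 0), 0)
  expect_error(estimate_g1(10, 11, 0), "inconsistent")
})

test_that("standard errors propagate to durations and shrink with noise", {
  set.seed(403)
  ph <- control_phases()
  t <- seq(3, 24, 3)
  n <- 800
  li_true <- expected_li(ph, 1, t)
  d <- data.frame(time_h = t, n_total = n,
                  n_labeled = rbinom(length(t), n, li_true))
  fit <- fit_labeling_curve(d, g = 1)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  # t_c = g/m: delta-method se must equal g*se_m/m^2
  expect_equal(unname(fit$se["t_c"]), fit$g * fit$se[["m"]] / fit$m^2,
               tolerance = 1e-12)
  expect_lt(abs(fit$t_c - ph$t_c), 4 * fit$se[["t_c"]])
})
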