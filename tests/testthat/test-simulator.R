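test_that("cohorts are deterministic per seed and honor the growth fraction", {
  spec <- population_spec(control_phases(), growth_fractions = 0.57)
  a <- simulate_cohort(spec, 10000, seed = 11)
  b <- simulate_cohort(spec, 10000, seed = 11)
  expect_identical(a, b)
  c2 <- simulate_cohort(spec, 10000, seed = 12)
  expect_false(identical(a$cycle_position, c2$cycle_position))
  # cycling fraction within 3 binomial sigma of 0.57 at n = 10,000
  expect_lt(abs(mean(a$cycling) - 0.57), 3 * sqrt(0.57 * 0.43 / 10000))
  expect_true(all(is.na(a$cycle_position[!a$cycling])))
})

test_that("a fully cycling cohort has no quiescent cells", {
  spec <- population_spec(control_phases())
  coh <- simulate_cohort(spec, 1000, seed = 1)
  expect_equal(sum(coh$cycling), 1000)
  expect_true(all(coh$cycle_position >= 0 &
                    coh$cycle_position < control_phases()$t_c))
})

test_that("cycle positions are age-uniform (KS bound)", {
  spec <- population_spec(control_phases())
  coh <- simulate_cohort(spec, 10000, seed = 21)
  u <- coh$cycle_position / control_phases()$t_c
  d_ks <- suppressWarnings(stats::ks.test(u, "punif")$statistic)
  expect_lt(unname(d_ks), 3 * sqrt(log(2) / 10000))
})

test_that("simulated cumulative labeling matches the closed form pointwise", {
  cases <- list(
    list(ph = control_phases(), g = 1),
    list(ph = cko_phases(), g = 1),
    list(ph = phase_durations(30, 10, 2, 1), g = 0.7)
  )
  times <- c(0.01, 3, 12, 24, 48)
  for (cs in cases) {
    spec <- population_spec(cs$ph, growth_fractions = cs$g)
    coh <- simulate_cohort(spec, 10000, seed = 31)
    curve <- run_cumulative_edu(coh, times)
    li_hat <- curve$n_labeled / curve$n_total
    li_exp <- expected_li(cs$ph, cs$g, times)
    se <- sqrt(pmax(li_exp * (1 - li_exp), 1e-6) / 10000)
    expect_true(all(abs(li_hat - li_exp) <= 3 * se))
  }
})

test_that("the labeling curve plateaus at the growth fraction and the
           counted population is constant", {
  ph <- phase_durations(20, 5, 1)  # t_c = 26
  spec <- population_spec(ph, growth_fractions = 1)
  coh <- simulate_cohort(spec, 5000, seed = 41)
  curve <- run_cumulative_edu(coh, c(1, 5, 21.5, 30, 60))
  expect_true(all(curve$n_total == 5000))          # steady-state renewal
  expect_equal(tail(curve$n_labeled, 3), rep(5000, 3))  # plateau at g = 1
})

test_that("a mixture's simulated labeling matches the weighted analytic mean", {
  # 80% slow (t_c = 205.1) + 20% fast (t_c = 77), equal S fraction
  slow <- phase_durations(205.1 * (1 - 13.5 / 77) - 5, 205.1 * 13.5 / 77, 5)
  fast <- phase_durations(61.7, 13.5, 1.8)
  spec <- population_spec(list(slow, fast), weights = c(0.8, 0.2))
  expect_equal(population_li(spec, 12),
               0.8 * expected_li(slow, 1, 12) + 0.2 * expected_li(fast, 1, 12))
  coh <- simulate_cohort(spec, 20000, seed = 51)
  curve <- run_cumulative_edu(coh, 12)
  li_exp <- population_li(spec, 12)
  expect_lt(abs(curve$n_labeled / curve$n_total - li_exp),
            3 * sqrt(li_exp * (1 - li_exp) / 20000))
})

test_that("mixture slope additivity: fitted pre-plateau slope is the
           weighted sum of subpopulation slopes", {
  ph1 <- phase_durations(100, 15, 2)
  ph2 <- phase_durations(40, 12, 2)
  w <- c(0.65, 0.35); g <- c(1, 0.8)
  spec <- population_spec(list(ph1, ph2), weights = w, growth_fractions = g)
  t <- seq(2, 30, length.out = 8)  # well before either plateau
  d <- data.frame(time_h = t, li = population_li(spec, t))
  fit <- fit_labeling_curve(d, g = 1)
  expect_equal(fit$m, sum(w * g / c(ph1$t_c, ph2$t_c)), tolerance = 1e-9)
})

test_that("pulse-chase pH3 fractions match the analytic labeled-mitoses flux", {
  # f_ph3 = min(t_m, t_chase - t_g2)/t_s while the front is past G2
  spec <- population_spec(phase_durations(59.3, 13.5, 2, 3))
  coh <- simulate_cohort(spec, 10000, seed = 61)
  obs <- run_pulse_chase(coh, t_chase = 4)
  f_exp <- (4 - 2) / 13.5
  expect_lt(abs(obs$f_ph3 - f_exp), 3 * sqrt(f_exp * (1 - f_exp) / obs$n_edu))
  # chase shorter than G2: no labeled cell has reached M
  obs0 <- run_pulse_chase(coh, t_chase = 1.5)
  expect_equal(obs0$f_ph3, 0)
  # labeled mitoses already divided: f_ph3 ~ t_m / t_s
  spec2 <- population_spec(phase_durations(61.5, 13.5, 2, 1))
  coh2 <- simulate_cohort(spec2, 10000, seed = 62)
  obs2 <- run_pulse_chase(coh2, t_chase = 4)
  f_exp2 <- 1 / 13.5
  expect_lt(abs(obs2$f_ph3 - f_exp2),
            3 * sqrt(f_exp2 * (1 - f_exp2) / obs2$n_edu))
})

test_that("G2 estimator is near-exact while the labeled front is in M,
           and biased upward once labeled mitoses have divided", {
  t_s <- 13.5
  # exact regime: t_chase <= t_g2 + t_m
  spec <- population_spec(phase_durations(59.3, t_s, 2, 3))
  coh <- simulate_cohort(spec, 10000, seed = 71)
  obs <- run_pulse_chase(coh, t_chase = 4)
  g2_hat <- as.numeric(estimate_g2(4, obs$f_ph3, t_s))
  expect_lt(abs(g2_hat - 2), 1)
  # biased regime: t_chase > t_g2 + t_m deflates f_ph3, inflating G2
  spec2 <- population_spec(phase_durations(61.5, t_s, 2, 1))
  coh2 <- simulate_cohort(spec2, 10000, seed = 72)
  obs2 <- run_pulse_chase(coh2, t_chase = 6)
  g2_hat2 <- as.numeric(estimate_g2(6, obs2$f_ph3, t_s))
  expect_gte(g2_hat2, 2)
})

test_that("stochastic parameter recovery: median fitted T_C within 15% of truth", {
  spec <- population_spec(control_phases())  # t_c = 76.6
  times <- seq(3, 24, by = 3)
  tc_hat <- vapply(1:20, function(s) {
    d <- simulate_labeling_experiment(spec, times, 500, seed = 1000 + s)
    fit_labeling_curve(d, g = 1)$t_c
  }, numeric(1))
  expect_lt(abs(stats::median(tc_hat) - 76.6) / 76.6, 0.15)
})

test_that("simulate_labeling_experiment is reproducible and windowed labeling
           caps the labeled fraction", {
  spec <- population_spec(control_phases())
  a <- simulate_labeling_experiment(spec, c(6, 12), 400, seed = 9)
  b <- simulate_labeling_experiment(spec, c(6, 12), 400, seed = 9)
  expect_identical(a, b)
  # with a 0-hour window only cells in S at t = 0 ever label
  coh <- simulate_cohort(spec, 10000, seed = 81)
  w0 <- run_cumulative_edu(coh, c(1, 24), pulse_window = 0)
  expect_equal(w0$n_labeled[1], w0$n_labeled[2])
  f_s <- 13.5 / 76.6
  expect_lt(abs(w0$n_labeled[1] / 10000 - f_s), 3 * sqrt(f_s * (1 - f_s) / 10000))
})
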