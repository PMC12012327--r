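#' Derive a child seed from a run seed
#'
#' All stochastic operations in a pipeline run derive their seeds
#' deterministically from one user-supplied integer, so a whole run is
#' reproducible from a single number. The derived seed is always a
#' nonnegative 32-bit integer.
#'
#' @param seed Integer run seed.
#' @param tag Character label of the consuming operation.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2011 + h %% 999983) %% 2147483645L
}

#' Simulate an asynchronous steady-state cohort
#'
#' Draws `n_cells` cells from a `population_spec`. Each cell is assigned a
#' subpopulation by weight; within its subpopulation a fraction equal to
#' the growth fraction is cycling, with cycle position uniform on
#' `[0, t_c)` — the age structure of a steady-state (constant-size)
#' asynchronous population with fixed phase durations. Non-cycling cells
#' are quiescent and carry no cycle position.
#'
#' @param spec A `population_spec`.
#' @param n_cells Number of cells, > 0.
#' @param seed Integer seed; the same seed yields an identical cohort.
#' @return An object of class `op_cohort`: a data frame with columns
#'   `subpopulation`, `cycling`, `cycle_position` (NA for quiescent cells),
#'   carrying the spec and seed as attributes.
#' @examples
#' spec <- population_spec(phase_durations(61.3, 13.5, 1.8))
#' coh <- simulate_cohort(spec, 1000, seed = 1)
#' mean(coh$cycling)  # 1: growth fraction defaults to 1
#' @export
simulate_cohort <- function(spec, n_cells, seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (n_cells <= 0) stop("`n_cells` must be > 0", call. = FALSE)
  set.seed(seed)
  sub <- sample.int(spec$n_subpop, n_cells, replace = TRUE, prob = spec$weights)
  g <- spec$growth_fractions[sub]
  cycling <- stats::runif(n_cells) < g
  tc <- vapply(spec$phases, `[[`, numeric(1), "t_c")[sub]
  pos <- ifelse(cycling, stats::runif(n_cells) * tc, NA_real_)
  out <- data.frame(subpopulation = sub, cycling = cycling,
                    cycle_position = pos)
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  class(out) <- c("op_cohort", "data.frame")
  out
}

# hours a cycling cell must wait before (re-)entering S-phase; 0 if in S now
time_to_s <- function(pos, t_g1, t_s, t_c) {
  in_s <- pos >= t_g1 & pos < t_g1 + t_s
  tts <- (t_g1 - pos) %% t_c
  tts[in_s] <- 0
  tts
}

cohort_phase_field <- function(cohort, field) {
  spec <- attr(cohort, "spec")
  vapply(spec$phases, `[[`, numeric(1), field)[cohort$subpopulation]
}

#' Simulate a cumulative-labeling experiment
#'
#' Exposes a cohort to EdU continuously from time 0 (or for
#' `pulse_window` hours) and counts labeled cells at each requested time.
#' A cell becomes EdU-positive the moment its trajectory enters S-phase
#' while label is available; the label is retained thereafter. Cells cycle
#' deterministically through their fixed phase schedule; on division one
#' daughter re-enters at cycle position 0, so the counted population is
#' stationary (steady-state renewal) — position arithmetic is modulo
#' `t_c`. Quiescent cells are counted in the denominator but never label,
#' so the curve plateaus at the growth fraction.
#'
#' Given the cohort, labeling is deterministic: all randomness lives in
#' the cohort draw.
#'
#' @param cohort An `op_cohort`.
#' @param times Sampling times (hours of label exposure), nonnegative.
#' @param pulse_window Label availability window (hours); `Inf` (default)
#'   for continuous cumulative labeling.
#' @return A data frame of class `labeling_curve` with columns `time_h`,
#'   `n_total`, `n_labeled`.
#' @examples
#' spec <- population_spec(phase_durations(61.3, 13.5, 1.8))
#' coh <- simulate_cohort(spec, 2000, seed = 7)
#' run_cumulative_edu(coh, times = c(3, 6, 12, 24))
#' @export
run_cumulative_edu <- function(cohort, times, pulse_window = Inf) {
  stopifnot(inherits(cohort, "op_cohort"))
  if (length(times) == 0 || any(times < 0)) {
    stop("`times` must be nonempty and nonnegative", call. = FALSE)
  }
  t_g1 <- cohort_phase_field(cohort, "t_g1")
  t_s <- cohort_phase_field(cohort, "t_s")
  t_c <- cohort_phase_field(cohort, "t_c")
  cyc <- cohort$cycling
  tts <- time_to_s(cohort$cycle_position[cyc], t_g1[cyc], t_s[cyc], t_c[cyc])
  n <- nrow(cohort)
  out <- data.frame(
    time_h = times,
    n_total = n,
    n_labeled = vapply(times, function(t) sum(tts <= min(t, pulse_window)),
                       numeric(1))
  )
  class(out) <- c("labeling_curve", "data.frame")
  out
}

#' Simulate a full cumulative-labeling study
#'
#' Convenience wrapper reflecting the design of a cumulative-labeling
#' study in vivo: each sampling time is an independent cohort (a different
#' litter), so counts at different times are independent draws. Child
#' seeds are derived deterministically from `seed`, one per timepoint.
#'
#' @param spec A `population_spec`.
#' @param times Sampling times (hours of exposure).
#' @param n_per_time Cells counted at each timepoint.
#' @param seed Integer run seed.
#' @param pulse_window Label availability window; `Inf` = continuous.
#' @return A `labeling_curve` data frame with one row per timepoint.
#' @examples
#' spec <- population_spec(phase_durations(61.3, 13.5, 1.8))
#' d <- simulate_labeling_experiment(spec, seq(3, 24, 3), 500, seed = 1)
#' fit_labeling_curve(d, g = 1)
#' @export
simulate_labeling_experiment <- function(spec, times, n_per_time, seed,
                                         pulse_window = Inf) {
  rows <- lapply(seq_along(times), function(i) {
    coh <- simulate_cohort(spec, n_per_time,
                           derive_seed(seed, paste0("timepoint", i)))
    run_cumulative_edu(coh, times[i], pulse_window)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("labeling_curve", "data.frame")
  out
}

#' Simulate a pulse-chase labeled-mitoses experiment
#'
#' Labels cells in S-phase during `[0, pulse_window]` (window 0 is an
#' instantaneous pulse: cells in S at time 0), advances every cycling cell
#' by `t_chase` hours (modulo its cycle), and scores pH3 positivity as
#' occupancy of M-phase at that moment. Returns the counts among EdU+
#' cells that the G2 estimator consumes.
#'
#' @param cohort An `op_cohort`.
#' @param t_chase Chase duration (hours), > 0.
#' @param pulse_window EdU availability window (hours); 0 = instantaneous.
#' @return A list of class `pulse_chase_obs` with `t_chase_h`, `n_edu`,
#'   `n_edu_ph3` and the derived `f_ph3`.
#' @examples
#' spec <- population_spec(phase_durations(59.3, 13.5, 2, t_m = 3))
#' coh <- simulate_cohort(spec, 10000, seed = 3)
#' run_pulse_chase(coh, t_chase = 4)$f_ph3   # ~ (4 - 2) / 13.5
#' @export
run_pulse_chase <- function(cohort, t_chase, pulse_window = 0) {
  stopifnot(inherits(cohort, "op_cohort"))
  if (t_chase <= 0) stop("`t_chase` must be > 0", call. = FALSE)
  t_g1 <- cohort_phase_field(cohort, "t_g1")
  t_s <- cohort_phase_field(cohort, "t_s")
  t_g2 <- cohort_phase_field(cohort, "t_g2")
  t_c <- cohort_phase_field(cohort, "t_c")
  cyc <- which(cohort$cycling)
  pos <- cohort$cycle_position[cyc]
  tts <- time_to_s(pos, t_g1[cyc], t_s[cyc], t_c[cyc])
  edu <- tts <= pulse_window
  new_pos <- (pos[edu] + t_chase) %% t_c[cyc][edu]
  m_start <- (t_g1 + t_s + t_g2)[cyc][edu]
  ph3 <- new_pos >= m_start & new_pos < t_c[cyc][edu]
  n_edu <- sum(edu)
  out <- list(t_chase_h = t_chase, n_edu = n_edu, n_edu_ph3 = sum(ph3),
              f_ph3 = if (n_edu > 0) sum(ph3) / n_edu else NA_real_)
  class(out) <- "pulse_chase_obs"
  out
}

#' @export
print.pulse_chase_obs <- function(x, ...) {
  cat(sprintf("Pulse-chase (%g h): %d EdU+, %d EdU+pH3+ (f_ph3 = %.4f)\n",
              x$t_chase_h, x$n_edu, x$n_edu_ph3, x$f_ph3))
  invisible(x)
}
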