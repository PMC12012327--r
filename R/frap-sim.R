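#' Parameters for simulated photobleaching traces
#'
#' Ground-truth parameters used by [generate_frap_trace()] and
#' [generate_flip_trace()]. Defaults mirror a typical confocal protocol:
#' 10 pre-bleach frames, then post-bleach imaging at 2 Hz
#' (`frame_interval = 0.5` s) for ~62 s.
#'
#' @param mobile_fraction Fraction of the fluorophore free to exchange,
#'   in \[0, 1\]. The immobile remainder is chromatin-bound.
#' @param rate_k Exchange rate constant (/s); recovery half-time is
#'   `log(2) / rate_k`.
#' @param bleach_depth Fractional intensity remaining in the bleach ROI
#'   immediately after the pulse, in (0, 1).
#' @param acquisition_bleach_rate Rate (/s) of the slow photobleaching
#'   shared by the bleach and reference ROIs during imaging.
#' @param noise_sd Additive Gaussian noise s.d., as a fraction of the
#'   pre-bleach signal intensity.
#' @param n_prebleach,n_postbleach Frame counts (>= 3 and >= 5).
#' @param frame_interval Seconds between frames.
#' @return An object of class `frap_sim_params`.
#' @export
frap_sim_params <- function(mobile_fraction, rate_k, bleach_depth = 0.3,
                            acquisition_bleach_rate = 0, noise_sd = 0,
                            n_prebleach = 10, n_postbleach = 124,
                            frame_interval = 0.5) {
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    stop("`mobile_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (bleach_depth <= 0 || bleach_depth >= 1) {
    stop("`bleach_depth` must lie in (0, 1)", call. = FALSE)
  }
  if (rate_k < 0 || acquisition_bleach_rate < 0 || noise_sd < 0) {
    stop("rates and noise must be >= 0", call. = FALSE)
  }
  if (n_prebleach < 3 || n_postbleach < 5) {
    stop("need >= 3 pre-bleach and >= 5 post-bleach frames", call. = FALSE)
  }
  if (frame_interval <= 0) stop("`frame_interval` must be > 0", call. = FALSE)
  structure(list(mobile_fraction = mobile_fraction, rate_k = rate_k,
                 bleach_depth = bleach_depth,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 noise_sd = noise_sd, n_prebleach = n_prebleach,
                 n_postbleach = n_postbleach, frame_interval = frame_interval),
            class = "frap_sim_params")
}

# common scaffolding: times, acquisition decay, noise, assembly into a trace
build_trace <- function(params, signal, seed) {
  set.seed(seed)
  p <- params
  n <- p$n_prebleach + p$n_postbleach
  t <- (seq_len(n) - 1) * p$frame_interval
  i0 <- 1000
  bg <- 100
  decay <- exp(-p$acquisition_bleach_rate * t)
  roi <- bg + i0 * signal * decay + stats::rnorm(n, 0, p$noise_sd * i0)
  reference <- bg + i0 * decay + stats::rnorm(n, 0, p$noise_sd * i0)
  frap_trace(t = t, roi = roi, reference = reference,
             background = rep(bg, n), bleach_index = p$n_prebleach + 1L)
}

#' Generate a synthetic FRAP trace
#'
#' Pre-bleach plateau at full intensity; a single bleaching pulse drops the
#' ROI to `bleach_depth`; recovery follows
#' `bleach_depth + mobile_fraction * (1 - bleach_depth) * (1 - exp(-k t))`
#' toward the level set by the planted mobile fraction. Both ROI and
#' reference decay by `exp(-acquisition_bleach_rate * t)` (shared imaging
#' bleach, which normalization must cancel), sit on a constant background,
#' and carry additive Gaussian noise. Deterministic for a fixed seed.
#'
#' @param params A `frap_sim_params`.
#' @param seed Integer seed.
#' @return A [frap_trace()] object.
#' @examples
#' tr <- generate_frap_trace(frap_sim_params(0.67, 0.1), seed = 1)
#' @export
generate_frap_trace <- function(params, seed) {
  stopifnot(inherits(params, "frap_sim_params"))
  p <- params
  tpost <- (seq_len(p$n_postbleach) - 1) * p$frame_interval
  rec <- p$bleach_depth +
    p$mobile_fraction * (1 - p$bleach_depth) * (1 - exp(-p$rate_k * tpost))
  build_trace(p, c(rep(1, p$n_prebleach), rec), seed)
}

#' Generate a synthetic FLIP trace
#'
#' Fluorescence loss in photobleaching: a spot elsewhere in the nucleus is
#' bleached continuously and the distal ROI loses signal as its mobile
#' pool exchanges through the bleached spot. The distal signal decays as
#' `(1 - mobile_fraction) + mobile_fraction * exp(-k t)`: the immobile
#' fraction is retained, the mobile fraction drains exponentially.
#' Acquisition bleaching, background and noise as in
#' [generate_frap_trace()]. `bleach_depth` is not used (the measured ROI
#' is outside the bleached spot).
#'
#' @inheritParams generate_frap_trace
#' @return A [frap_trace()] object.
#' @export
generate_flip_trace <- function(params, seed) {
  stopifnot(inherits(params, "frap_sim_params"))
  p <- params
  tpost <- (seq_len(p$n_postbleach) - 1) * p$frame_interval
  loss <- (1 - p$mobile_fraction) + p$mobile_fraction * exp(-p$rate_k * tpost)
  build_trace(p, c(rep(1, p$n_prebleach), loss), seed)
}
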