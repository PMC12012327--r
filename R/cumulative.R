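#' Fit a cumulative-labeling time course
#'
#' Estimates total cell-cycle time and S-phase duration from a cumulative
#' EdU (or BrdU) labeling experiment. Under continuous label availability
#' the labeling index L.I. of an asynchronous steady-state population rises
#' linearly with exposure time, `L.I.(t) = y0 + m * t`, until it reaches an
#' abrupt plateau at the growth fraction G. The cycle time is `T_C = G / m`
#' and the S-phase duration `T_S = y0 * G / m`.
#'
#' The fit is a weighted least-squares line through the pre-plateau points.
#' Points with observed L.I. at or above `g * (1 - plateau_tol)` are treated
#' as plateau and excluded (the linear model only holds on the rise).
#' Weights are inverse binomial variances, `n_total / (li * (1 - li) + eps)`
#' with `eps = 1 / (4 * n_total)` so that points at L.I. 0 or 1 keep a
#' finite weight.
#'
#' When `g = "auto"`, the growth fraction is taken to be the maximum
#' observed L.I. provided at least two points lie within `plateau_tol` of
#' that maximum (i.e. the plateau was actually sampled); otherwise G
#' defaults to 1, the value measured for perinatal OP populations.
#'
#' @param data A data frame with columns `time_h`, `n_total`, `n_labeled`
#'   (counts may be non-integer effective counts), or `time_h` and `li`.
#' @param g Growth fraction in (0, 1\], or `"auto"` (default).
#' @param plateau_tol Relative tolerance used both to flag plateau points
#'   and to resolve `g = "auto"`. Default 0.02.
#'
#' @return An object of class `cumlab_fit` with components `m`, `y0`, `g`,
#'   `t_c`, `t_s`, standard errors `se` (first-order propagation using the
#'   full coefficient covariance), `n_points_used`, `excluded` (indices of
#'   plateau points), `plateau_reached`, the underlying `lm` fit, and the
#'   augmented data. Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`, `simulate`.
#'
#' @examples
#' t <- c(3, 6, 12, 18, 24)
#' d <- data.frame(time_h = t, li = 0.1 + 0.01 * t)
#' fit <- fit_labeling_curve(d, g = 1)
#' coef(fit)        # m = 0.01, y0 = 0.1
#' fit$t_c          # 100 h
#' @seealso [estimate_tc_ts()], [expected_li()], [simulate_cohort()]
#' @export
fit_labeling_curve <- function(data, g = "auto", plateau_tol = 0.02) {
  data <- as.data.frame(data)
  if (!"time_h" %in% names(data)) stop("`data` needs a `time_h` column", call. = FALSE)
  if (all(c("n_total", "n_labeled") %in% names(data))) {
    validate_counts(data$time_h, data$n_total, data$n_labeled)
    data$li <- data$n_labeled / data$n_total
  } else if ("li" %in% names(data)) {
    if (any(data$li < 0 | data$li > 1)) stop("`li` must lie in [0, 1]", call. = FALSE)
    if (is.null(data$n_total)) data$n_total <- 1
  } else {
    stop("`data` needs either `n_total` + `n_labeled` or `li`", call. = FALSE)
  }
  if (any(data$time_h < 0)) stop("`time_h` must be >= 0", call. = FALSE)

  g_mode <- if (identical(g, "auto")) "auto" else "fixed"
  if (g_mode == "auto") {
    max_li <- max(data$li)
    near_max <- data$li >= max_li * (1 - plateau_tol)
    g <- if (sum(near_max) >= 2 && max_li > 0) max_li else 1
  } else {
    g <- as.numeric(g)
    if (!is.finite(g) || g <= 0 || g > 1) stop("`g` must lie in (0, 1]", call. = FALSE)
  }

  plateau <- data$li >= g * (1 - plateau_tol)
  use <- !plateau
  if (all(plateau)) {
    stop("all points are at the plateau; the linear rise is not sampled",
         call. = FALSE)
  }
  if (sum(use) < 2 || length(unique(data$time_h[use])) < 2) {
    stop("need at least 2 pre-plateau points with distinct times", call. = FALSE)
  }

  eps <- 1 / (4 * data$n_total)
  w <- data$n_total / (data$li * (1 - data$li) + eps)
  d_use <- data[use, , drop = FALSE]
  lmfit <- stats::lm(li ~ time_h, data = d_use, weights = w[use])
  cf <- stats::coef(lmfit)
  y0 <- unname(cf[1]); m <- unname(cf[2])
  if (!is.finite(m) || m <= 0) {
    stop("non-identifiable fit: slope m must be > 0", call. = FALSE)
  }
  if (y0 < 0) warning("fitted intercept y0 < 0; T_S estimate clipped at 0")

  # suppressWarnings: noise-free data trigger lm's "essentially perfect fit"
  V <- suppressWarnings(stats::vcov(lmfit))  # (y0, m)
  if (any(!is.finite(V))) V <- matrix(0, 2, 2)
  t_c <- g / m
  t_s <- max(y0, 0) * g / m
  # first-order (delta-method) propagation with coefficient covariance
  g_tc <- c(0, -g / m^2)
  g_ts <- c(g / m, -y0 * g / m^2)
  se <- c(m = sqrt(V[2, 2]), y0 = sqrt(V[1, 1]),
          t_c = sqrt(drop(t(g_tc) %*% V %*% g_tc)),
          t_s = sqrt(drop(t(g_ts) %*% V %*% g_ts)))

  data$weight <- w
  data$used <- use
  structure(list(m = m, y0 = y0, g = g, g_mode = g_mode,
                 t_c = t_c, t_s = t_s, se = se, vcov = V,
                 n_points_used = sum(use), excluded = which(plateau),
                 plateau_reached = any(plateau), plateau_tol = plateau_tol,
                 data = data, lm = lmfit, call = match.call()),
            class = "cumlab_fit")
}

validate_counts <- function(t, n_total, n_labeled) {
  bad <- which(!is.finite(n_total) | n_total <= 0)
  if (length(bad)) stop(sprintf("row %d: n_total must be > 0", bad[1]), call. = FALSE)
  bad <- which(!is.finite(n_labeled) | n_labeled < 0 | n_labeled > n_total)
  if (length(bad)) {
    stop(sprintf("row %d: n_labeled must lie in [0, n_total]", bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cycle and S-phase time from slope and intercept
#'
#' Direct algebraic conversion of a cumulative-labeling line to durations:
#' `t_c = g / m` and `t_s = y0 * g / m`.
#'
#' @param m Slope of the labeling line (per hour); must be positive.
#' @param y0 Intercept (labeling index at t = 0).
#' @param g Growth fraction; `0 <= y0 < g <= 1`.
#' @return Named numeric vector `c(t_c = , t_s = )`, hours.
#' @examples
#' estimate_tc_ts(m = 0.013055, y0 = 0.17624, g = 1)  # ~ c(76.6, 13.5)
#' @export
estimate_tc_ts <- function(m, y0, g = 1) {
  if (!is.finite(m) || m <= 0) stop("`m` must be > 0", call. = FALSE)
  if (y0 < 0 || y0 >= g || g > 1) stop("need 0 <= y0 < g <= 1", call. = FALSE)
  c(t_c = g / m, t_s = y0 * g / m)
}

#' @export
print.cumlab_fit <- function(x, ...) {
  cat("Cumulative-labeling fit\n")
  cat(sprintf("  m  = %.6g /h   y0 = %.6g   G = %.4g (%s)\n",
              x$m, x$y0, x$g, x$g_mode))
  cat(sprintf("  T_C = %s h   T_S = %s h\n",
              format_duration(x$t_c), format_duration(x$t_s)))
  if (x$plateau_reached) {
    cat(sprintf("  %d plateau point(s) excluded from the fit\n",
                length(x$excluded)))
  }
  invisible(x)
}

#' @export
summary.cumlab_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cumlab_fit")
}

#' @export
print.summary.cumlab_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  se(m) = %.3g, se(y0) = %.3g\n", f$se["m"], f$se["y0"]))
  cat(sprintf("  T_C = %.4g +/- %.3g h,  T_S = %.4g +/- %.3g h\n",
              f$t_c, f$se["t_c"], f$t_s, f$se["t_s"]))
  cat(sprintf("  points used: %d of %d\n", f$n_points_used, nrow(f$data)))
  invisible(x)
}

#' @export
coef.cumlab_fit <- function(object, ...) {
  c(m = object$m, y0 = object$y0)
}

#' @export
predict.cumlab_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_h else newdata$time_h
  pmin(object$y0 + object$m * t, object$g)
}

#' @export
residuals.cumlab_fit <- function(object, ...) {
  object$data$li - predict(object)
}

#' @export
plot.cumlab_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$time_h, d$li, pch = ifelse(d$used, 19, 1),
                 xlab = "EdU exposure time (h)", ylab = "Labeling index",
                 ylim = c(0, max(1, max(d$li))), ...)
  tt <- seq(0, max(d$time_h) * 1.05, length.out = 200)
  graphics::lines(tt, pmin(x$y0 + x$m * tt, x$g))
  graphics::abline(h = x$g, lty = 3)
  invisible(x)
}

#' Parametric bootstrap of a labeling curve fit
#'
#' Draws binomial labeled counts at the design times from the fitted line,
#' using the observed `n_total` at each point.
#'
#' @param object A `cumlab_fit`.
#' @param nsim Number of simulated data sets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `time_h`, `n_total`,
#'   `n_labeled`.
#' @export
simulate.cumlab_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  n <- pmax(round(d$n_total), 1)
  p <- predict(object)
  lapply(seq_len(nsim), function(i) {
    data.frame(time_h = d$time_h, n_total = n,
               n_labeled = stats::rbinom(length(n), n, p))
  })
}
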