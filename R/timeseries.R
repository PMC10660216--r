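#' Fit a fixed-period sinusoid to a seasonal series
#'
#' Fits \eqn{y(x) = A \sin(2\pi(x + \phi)/P) + C} with the period \eqn{P}
#' fixed (12 months by default, the annual cycle), which makes the fit an
#' ordinary linear regression: \eqn{y = \beta_1 \sin(2\pi x/P) + \beta_2
#' \cos(2\pi x/P) + C}.  Amplitude and phase are recovered in closed form
#' (\eqn{A = \sqrt{\beta_1^2+\beta_2^2}}, \eqn{\phi} from the two-argument
#' arctangent) and canonicalised to \eqn{A \ge 0}, \eqn{\phi \in [0, P)},
#' resolving the sign/phase aliasing deterministically.  No iteration and
#' no random number is involved.  When the fitted amplitude is numerically
#' zero the phase is unidentifiable and returned as 0 by convention.
#'
#' @param data A data frame of one observation per row.
#' @param time Column of observation times, in the same units as `period`
#'   (months for the annual default).  Defaults to a column named
#'   `time_months`.
#' @param value Column of observed values.  Defaults to a column named
#'   `value`.
#' @param period Fixed period, same units as `time`; default 12 months.
#' @return A `sine_fit` object with elements `amplitude`, `phase`,
#'   `offset`, `period`, `rss`, `n` and the model data; see methods
#'   [tidy.sine_fit()], [glance.sine_fit()], [predict.sine_fit()],
#'   [autoplot.sine_fit()] and [phase_lag()].
#' @examples
#' monthly <- tibble::tibble(
#'   time_months = 0:11,
#'   value = 2 * sin(2 * pi * (0:11 + 3) / 12) + 10
#' )
#' fit_sine(monthly)
#' @export
fit_sine <- function(data, time = time_months, value = value, period = 12) {
  if (!is.numeric(period) || length(period) != 1 || period <= 0) {
    abort("`period` must be a single positive number")
  }
  x <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ value }})
  if (length(x) != length(y) || length(x) < 3) {
    abort("need at least 3 paired (time, value) observations")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("missing values in `time` or `value`")
  }
  w <- 2 * pi / period
  mm <- cbind(1, sin(w * x), cos(w * x))
  if (qr(mm)$rank < 3) {
    abort(paste0(
      "underdetermined design: sample times do not identify the ",
      "sinusoid (all congruent modulo the period?)"
    ))
  }
  fit <- lm.fit(mm, y)
  b <- fit$coefficients
  amplitude <- sqrt(b[[2]]^2 + b[[3]]^2)
  # y = b2 sin(wx) + b3 cos(wx) = A sin(w(x + phase)) with
  # b2 = A cos(w phase), b3 = A sin(w phase)
  tol <- 1e-10 * max(abs(y), 1)
  phase <- if (amplitude < tol) 0 else (atan2(b[[3]], b[[2]]) / w) %% period
  structure(
    list(
      amplitude = amplitude,
      phase = phase,
      offset = b[[1]],
      period = period,
      rss = sum(fit$residuals^2),
      n = length(x),
      data = tibble(time = x, value = y)
    ),
    class = "sine_fit"
  )
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf(
    "Fixed-period sine fit: y = %.4g * sin(2*pi*(x + %.4g)/%.4g) + %.4g\n",
    x$amplitude, x$phase, x$period, x$offset
  ))
  cat(sprintf("  n = %d, RSS = %.4g\n", x$n, x$rss))
  invisible(x)
}

#' Tidy and summary views of a sine fit
#'
#' @param x A `sine_fit` from [fit_sine()].
#' @param ... Unused.
#' @return `tidy()` gives one row per parameter (amplitude, phase, offset);
#'   `glance()` gives a one-row fit summary.
#' @export
tidy.sine_fit <- function(x, ...) {
  tibble(
    term = c("amplitude", "phase", "offset"),
    estimate = c(x$amplitude, x$phase, x$offset)
  )
}

#' @rdname tidy.sine_fit
#' @export
glance.sine_fit <- function(x, ...) {
  tibble(
    amplitude = x$amplitude, phase = x$phase, offset = x$offset,
    period = x$period, rss = x$rss, n = x$n
  )
}

#' Evaluate a fitted sinusoid
#'
#' @param object A `sine_fit`.
#' @param newdata Numeric vector of times, or a data frame with a `time`
#'   column; defaults to the training times.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.sine_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$time
  } else if (is.data.frame(newdata)) {
    newdata$time
  } else {
    newdata
  }
  object$amplitude * sin(2 * pi * (x + object$phase) / object$period) +
    object$offset
}

#' Plot a sine fit over its data
#'
#' @param object A `sine_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sine_fit <- function(object, ...) {
  grid <- tibble(
    time = seq(min(object$data$time), max(object$data$time), length.out = 200)
  )
  grid$value <- predict(object, grid$time)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#00798c") +
    ggplot2::labs(
      x = "time (months)", y = "value",
      title = sprintf(
        "y = %.3g sin(2π(x + %.3g)/%.3g) + %.3g",
        object$amplitude, object$phase, object$period, object$offset
      )
    ) +
    ggplot2::theme_minimal()
}

#' Phase lag between two fitted seasonal cycles
#'
#' The smallest-magnitude signed lag \eqn{\lambda \in (-P/2, P/2]} such
#' that cycle `a` peaks \eqn{\lambda} time units after cycle `b`, computed
#' as the wrapped difference of the fitted phases.  Positive means the
#' first series lags the second — e.g. a community-composition cycle that
#' trails the water-temperature cycle gives a positive lag.
#'
#' @param fit_a,fit_b `sine_fit` objects with identical periods.
#' @return Signed lag in the time units of the fits (months for the annual
#'   default).
#' @examples
#' m <- tibble::tibble(t = seq(0, 11.5, 0.5))
#' mpt <- fit_sine(dplyr::mutate(m, y = 1.9 * sin(2 * pi * (t + 4.2) / 12) + 21), t, y)
#' wat <- fit_sine(dplyr::mutate(m, y = 7 * sin(2 * pi * (t + 6.1) / 12) + 13.9), t, y)
#' phase_lag(mpt, wat) # +1.9: the community cycle trails the water cycle
#' @export
phase_lag <- function(fit_a, fit_b) {
  if (!inherits(fit_a, "sine_fit") || !inherits(fit_b, "sine_fit")) {
    abort("`fit_a` and `fit_b` must be sine_fit objects")
  }
  p <- fit_a$period
  if (!isTRUE(all.equal(p, fit_b$period))) {
    abort("cannot compare fits with different periods")
  }
  lag <- (fit_b$phase - fit_a$phase + p / 2) %% p - p / 2
  if (lag == -p / 2) lag <- p / 2
  lag
}

#' Read a (time, value) series from a TSV file
#'
#' Expects columns `time_months` and `value` (additional columns are kept).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_timeseries <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_months", "value") %in% names(out))) {
    abort("time-series TSV must have columns `time_months` and `value`")
  }
  out
}
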