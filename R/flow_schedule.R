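#' Power-law drainage trendline
#'
#' Post-operative drainage after knee revision declines roughly as a power law
#' of time. The trendline `flow = a * t^b` (flow in mL/min, `t` in hours)
#' summarises clinically observed drainage rates; the default coefficients are
#' the fit used to drive the reactor pump. Because `b < 0` the curve diverges
#' as `t -> 0`, so any schedule built from it must cap the initial flow.
#'
#' @param coefficient Flow rate at unit time (`t = 1` hour), mL/min. Must be
#'   positive. Default 3.1269.
#' @param exponent Dimensionless power-law exponent, must be negative.
#'   Default -1.019.
#' @param time_unit Unit of the time axis, `"hours"` (default) or `"minutes"`.
#'   Carried so alternate fits can be represented explicitly.
#' @return An object of class `drainage_trendline`.
#' @seealso [evaluate_trendline()], [fit_power_law()],
#'   [build_stepwise_schedule()]
#' @export
#' @examples
#' tl <- drainage_trendline()
#' evaluate_trendline(tl, c(1, 2, 24))
drainage_trendline <- function(coefficient = 3.1269, exponent = -1.019,
                               time_unit = c("hours", "minutes")) {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L,
            is.finite(coefficient), coefficient > 0)
  stopifnot(is.numeric(exponent), length(exponent) == 1L, is.finite(exponent))
  if (exponent >= 0) {
    stop("drainage trendline exponent must be negative (flow declines in time)",
         call. = FALSE)
  }
  structure(
    list(coefficient = coefficient, exponent = exponent,
         time_unit = match.arg(time_unit)),
    class = "drainage_trendline"
  )
}

#' @export
print.drainage_trendline <- function(x, ...) {
  cat(sprintf("Drainage trendline: flow = %g * t^%g  [mL/min, t in %s]\n",
              x$coefficient, x$exponent, x$time_unit))
  invisible(x)
}

#' Evaluate a drainage trendline
#'
#' Returns `a * t^b` mL/min. The curve diverges as `t -> 0+`, so non-positive
#' times are a domain error.
#'
#' @param trendline A [drainage_trendline()].
#' @param t Time(s), in the trendline's `time_unit`; all must be `> 0`.
#' @return Flow rate(s), mL/min.
#' @export
evaluate_trendline <- function(trendline, t) {
  stopifnot(inherits(trendline, "drainage_trendline"), is.numeric(t))
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("trendline is only defined for t > 0 (flow diverges at t = 0)",
         call. = FALSE)
  }
  trendline$coefficient * t^trendline$exponent
}

#' Fit a power-law trendline to clinical drainage observations
#'
#' Ordinary least squares on `log(flow) ~ log(time)`, the standard fit for a
#' power-law trendline under multiplicative error. The slope is the exponent
#' and the exponentiated intercept the coefficient.
#'
#' @param points Data frame with columns `time_h` (> 0) and `flow_ml_min`
#'   (> 0), e.g. from [read_drainage_points()].
#' @return A [drainage_trendline()].
#' @export
#' @examples
#' pts <- data.frame(time_h = c(1, 4), flow_ml_min = c(4, 1))
#' fit_power_law(pts) # exponent -1, coefficient 4
fit_power_law <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("time_h", "flow_ml_min") %in% names(points)))
  tt <- points$time_h
  ff <- points$flow_ml_min
  if (any(!is.finite(tt)) || any(tt <= 0)) {
    stop("drainage times must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(ff)) || any(ff <= 0)) {
    stop("drainage flows must be positive for a log-log fit", call. = FALSE)
  }
  if (length(unique(tt)) < 2L) {
    stop("need at least 2 distinct observation times to fit a trendline",
         call. = FALSE)
  }
  fit <- stats::lm(log(ff) ~ log(tt))
  co <- stats::coef(fit)
  drainage_trendline(coefficient = exp(unname(co[1L])),
                     exponent = unname(co[2L]))
}

#' Effluent sampling times used on the bench
#'
#' Samples were drawn every 5 minutes for the first 55 minutes, then hourly
#' from 1 to 8 h, and at 12, 18, 24 and 48 h: 23 time points in total.
#'
#' @return Numeric vector of 23 sampling times, hours.
#' @export
default_sampling_times <- function() {
  c((1:11) * 5 / 60, 1:8, 12, 18, 24, 48)
}

#' Discretize the trendline into a stepwise pump schedule
#'
#' A peristaltic pump cannot follow a continuous curve, so the trendline is
#' discretized into piecewise-constant steps. Each step takes the trendline
#' value at its start time, capped at `initial_cap`; the first step (starting
#' at 0, where the curve diverges) runs at the cap, mirroring the visual
#' back-extrapolation of the initial flow to 3.5 mL/min. Step intervals are
#' half-open `[start, end)`.
#'
#' @param trendline A [drainage_trendline()].
#' @param boundaries Strictly increasing step-boundary times in `(0, duration]`,
#'   hours. Defaults to the effluent sampling times. An empty vector gives a
#'   single constant step at `initial_cap`.
#' @param initial_cap Maximum (initial) flow, mL/min. Default 3.5.
#' @param duration Schedule duration, hours. Default 48.
#' @return An object of class `stepwise_schedule`: a data frame of steps
#'   (`start_h`, `end_h`, `flow_ml_min`) with attributes `initial_cap` and
#'   `duration`.
#' @export
#' @examples
#' sched <- build_stepwise_schedule(drainage_trendline())
#' flow_at(sched, c(10 / 60, 1, 24)) # 3.5, 3.1269, ...
build_stepwise_schedule <- function(trendline,
                                    boundaries = default_sampling_times(),
                                    initial_cap = 3.5, duration = 48) {
  stopifnot(inherits(trendline, "drainage_trendline"),
            is.numeric(initial_cap), length(initial_cap) == 1L,
            initial_cap > 0,
            is.numeric(duration), length(duration) == 1L, duration > 0)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries)) {
    if (any(diff(boundaries) <= 0)) {
      stop("step boundaries must be strictly increasing", call. = FALSE)
    }
    if (boundaries[1L] <= 0 || boundaries[length(boundaries)] > duration) {
      stop("step boundaries must lie in (0, duration]", call. = FALSE)
    }
  }
  starts <- c(0, boundaries[boundaries < duration])
  ends <- c(starts[-1L], duration)
  flow <- c(initial_cap,
            if (length(starts) > 1L) {
              pmin(initial_cap, evaluate_trendline(trendline, starts[-1L]))
            })
  steps <- data.frame(start_h = starts, end_h = ends, flow_ml_min = flow)
  structure(steps, class = c("stepwise_schedule", "data.frame"),
            initial_cap = initial_cap, duration = duration)
}

#' Constant-flow schedule
#'
#' Convenience constructor for a single-step schedule at a fixed flow rate,
#' used for closed-form washout checks and simple scenarios.
#'
#' @param flow_ml_min Constant flow, mL/min (>= 0; zero gives a closed,
#'   unflushed vessel).
#' @param duration Duration, hours.
#' @return A `stepwise_schedule` with one step.
#' @export
constant_schedule <- function(flow_ml_min, duration = 48) {
  stopifnot(is.numeric(flow_ml_min), length(flow_ml_min) == 1L,
            flow_ml_min >= 0, duration > 0)
  steps <- data.frame(start_h = 0, end_h = duration, flow_ml_min = flow_ml_min)
  structure(steps, class = c("stepwise_schedule", "data.frame"),
            initial_cap = flow_ml_min, duration = duration)
}

#' @export
print.stepwise_schedule <- function(x, ...) {
  cat(sprintf("Stepwise drainage schedule: %d steps over %g h, cap %g mL/min\n",
              nrow(x), attr(x, "duration"), attr(x, "initial_cap")))
  print.data.frame(utils::head(as.data.frame(x), 8L), row.names = FALSE)
  if (nrow(x) > 8L) cat(sprintf("... %d more steps\n", nrow(x) - 8L))
  invisible(x)
}

#' Schedule duration in hours
#' @param schedule A `stepwise_schedule`.
#' @return Duration, hours.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "stepwise_schedule"))
  attr(schedule, "duration")
}

#' Pump flow rate at given times
#'
#' Looks up the step whose half-open interval `[start, end)` contains `t`;
#' `t = duration` maps to the final step.
#'
#' @param schedule A `stepwise_schedule`.
#' @param t Time(s) in `[0, duration]`, hours.
#' @return Flow rate(s), mL/min.
#' @export
flow_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "stepwise_schedule"), is.numeric(t))
  dur <- attr(schedule, "duration")
  if (any(!is.finite(t)) || any(t < 0) || any(t > dur)) {
    stop(sprintf("time outside the schedule range [0, %g] h", dur),
         call. = FALSE)
  }
  idx <- findInterval(t, schedule$start_h)
  schedule$flow_ml_min[pmax(1L, idx)]
}

#' Cumulative drained volume
#'
#' Integrates the stepwise flow from 0 to `t` (exact for piecewise-constant
#' flow), converting mL/min to per-hour volume. Supports mass-balance audits.
#'
#' @param schedule A `stepwise_schedule`.
#' @param t Time(s) in `[0, duration]`, hours.
#' @return Cumulative volume(s), mL.
#' @export
cumulative_volume <- function(schedule, t) {
  stopifnot(inherits(schedule, "stepwise_schedule"), is.numeric(t))
  dur <- attr(schedule, "duration")
  if (any(!is.finite(t)) || any(t < 0) || any(t > dur)) {
    stop(sprintf("time outside the schedule range [0, %g] h", dur),
         call. = FALSE)
  }
  vapply(t, function(ti) {
    overlap <- pmax(0, pmin(schedule$end_h, ti) - schedule$start_h)
    sum(schedule$flow_ml_min * 60 * overlap)
  }, numeric(1L))
}

#' Read clinical drainage observations from CSV
#'
#' Expects a header with columns `time_h` and `flow_ml_min`.
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns `time_h`, `flow_ml_min`.
#' @export
read_drainage_points <- function(path) {
  df <- utils::read.csv(path)
  req <- c("time_h", "flow_ml_min")
  if (!all(req %in% names(df))) {
    stop("drainage CSV must have columns time_h and flow_ml_min",
         call. = FALSE)
  }
  df[req]
}

#' Export a stepwise schedule to CSV
#'
#' Columns `start_h`, `end_h`, `flow_ml_min`.
#'
#' @param schedule A `stepwise_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "stepwise_schedule"))
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}
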