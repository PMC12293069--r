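# Scalar summaries of simulated trajectories: peaks, AUCs, crossing times,
# invaded fractions, clearance.

#' Peak of a state variable
#'
#' Locates the maximum of the named variable over the reporting grid and
#' refines value and time by fitting a quadratic through the grid maximum and
#' its two neighbours (skipped at the grid boundary or when the neighbours do
#' not bracket a concave peak). Ties are broken at the earliest time.
#'
#' @param traj A `"trajectory"`.
#' @param variable One of [state_names()], or `"T_total"` for `T_U + T_I`.
#' @return List with `value` and `time` (days).
#' @export
#' @examples
#' \donttest{
#' traj <- simulate_therapy(baseline_parameters(),
#'   baseline_initial_conditions("intratumoral", "cold", 1e6, 1e6))
#' traj_peak(traj, "T_I")  # invasion peaks about seven hours post-injection
#' }
traj_peak <- function(traj, variable) {
  y <- trajectory_variable(traj, variable)
  t <- traj$times
  k <- which.max(y)  # which.max returns the first (earliest) maximum
  value <- y[k]
  time <- t[k]
  if (k > 1L && k < length(y)) {
    # Quadratic through (t[k-1], y[k-1]), (t[k], y[k]), (t[k+1], y[k+1]).
    h1 <- t[k] - t[k - 1L]; h2 <- t[k + 1L] - t[k]
    d1 <- (y[k] - y[k - 1L]) / h1
    d2 <- (y[k + 1L] - y[k]) / h2
    curv <- (d2 - d1) / (h1 + h2) * 2
    if (curv < 0) {
      slope <- (d1 * h2 + d2 * h1) / (h1 + h2)
      dt <- -slope / curv
      if (abs(dt) <= max(h1, h2)) {
        time <- t[k] + dt
        value <- y[k] + slope * dt + curv * dt^2 / 2
      }
    }
  }
  list(value = value, time = time)
}

#' Area under a state variable's curve
#'
#' Trapezoidal integral of the named variable over a time window on the
#' reporting grid. Window endpoints falling between grid points are handled
#' by linear interpolation, so the integral is additive over adjacent
#' windows.
#'
#' @param traj A `"trajectory"`.
#' @param variable One of [state_names()] or `"T_total"`.
#' @param window Numeric `c(t_start, t_end)` in days, within the trajectory
#'   span, `t_start < t_end`. Default: the full span.
#' @return The integral in state-units * days.
#' @export
traj_auc <- function(traj, variable, window = NULL) {
  y <- trajectory_variable(traj, variable)
  t <- traj$times
  if (is.null(window)) window <- range(t)
  if (length(window) != 2L || !all(is.finite(window)) ||
      window[1L] >= window[2L]) {
    stop("window must be c(t_start, t_end) with t_start < t_end",
         call. = FALSE)
  }
  if (window[1L] < min(t) || window[2L] > max(t)) {
    stop(sprintf("window [%g, %g] outside trajectory span [%g, %g]",
                 window[1L], window[2L], min(t), max(t)), call. = FALSE)
  }
  inside <- t > window[1L] & t < window[2L]
  tt <- c(window[1L], t[inside], window[2L])
  yy <- c(stats::approx(t, y, xout = window[1L])$y, y[inside],
          stats::approx(t, y, xout = window[2L])$y)
  sum(diff(tt) * (yy[-length(yy)] + yy[-1L]) / 2)
}

#' Time to reach a fraction of carrying capacity
#'
#' Earliest time at which the total tumor burden `T_U + T_I` reaches
#' `fraction * (1/b)`, linearly interpolated between grid points. The model's
#' logistic asymptote is never attained exactly, so "reaching maximal
#' volume" is operationalized as a 95% threshold by default.
#'
#' @param traj A `"trajectory"`.
#' @param fraction Fraction of capacity in (0, 1). Default 0.95.
#' @param b Inverse carrying capacity; defaults to the trajectory's own `b`.
#' @return Crossing time in days, or `NA_real_` if never reached.
#' @export
time_to_fraction_of_capacity <- function(traj, fraction = 0.95, b = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  if (is.null(b)) b <- traj$params[["b"]]
  threshold <- fraction / b
  tot <- traj$states[, "T_U"] + traj$states[, "T_I"]
  k <- which(tot >= threshold)
  if (length(k) == 0L) return(NA_real_)
  k <- k[1L]
  if (k == 1L) return(traj$times[1L])
  # linear interpolation on the crossing segment
  t0 <- traj$times[k - 1L]; t1 <- traj$times[k]
  y0 <- tot[k - 1L]; y1 <- tot[k]
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}

#' Maximum invaded fraction
#'
#' Maximum over time of the invaded cell count `T_I` relative to either the
#' initial tumor burden (`"initial_tumor"`: `T_I(t) / (T_U(0) + T_I(0))`) or
#' the concurrent total (`"concurrent_total"`: `T_I(t) / (T_U(t) + T_I(t))`,
#' undefined segments with zero total excluded).
#'
#' @param traj A `"trajectory"`.
#' @param denominator `"initial_tumor"` or `"concurrent_total"`.
#' @return Dimensionless fraction in `[0, 1]` for sensible inputs.
#' @export
invaded_fraction_max <- function(traj,
                                 denominator = c("initial_tumor",
                                                 "concurrent_total")) {
  stopifnot(inherits(traj, "trajectory"))
  denominator <- match.arg(denominator)
  ti <- traj$states[, "T_I"]
  if (denominator == "initial_tumor") {
    denom <- traj$states[1L, "T_U"] + traj$states[1L, "T_I"]
    if (denom <= 0) stop("initial tumor burden is zero", call. = FALSE)
    return(max(ti / denom))
  }
  tot <- traj$states[, "T_U"] + traj$states[, "T_I"]
  ok <- tot > 0
  if (!any(ok)) stop("tumor burden is zero at every time point", call. = FALSE)
  max(ti[ok] / tot[ok])
}

#' Tumor clearance flag
#'
#' A tumor counts as cleared when the total burden `T_U + T_I` drops below
#' one cell at some time and never regrows above one cell afterwards
#' (sub-one counts are biologically extinct).
#'
#' @param traj A `"trajectory"`.
#' @param threshold Extinction threshold in cells (default 1).
#' @return Logical flag.
#' @export
is_cleared <- function(traj, threshold = 1) {
  stopifnot(inherits(traj, "trajectory"))
  tot <- traj$states[, "T_U"] + traj$states[, "T_I"]
  below <- which(tot < threshold)
  if (length(below) == 0L) return(FALSE)
  all(tot[below[1L]:length(tot)] < threshold)
}

#' Summary metrics of a trajectory
#'
#' Bundles the scalar summaries reported for a simulated treatment: peak
#' value/time of a focal variable, its AUC over a window, the time to 95% of
#' carrying capacity, the clearance flag, the maximum invaded fraction, and
#' the day-15 and day-30 total tumor burden (when within the horizon).
#'
#' @param traj A `"trajectory"`.
#' @param variable Focal state variable for peak and AUC (default `"T_I"`).
#' @param auc_window AUC window in days; default `c(0, 10)` (the window over
#'   which administration routes yield comparable invaded-cell exposure),
#'   truncated to the trajectory span.
#' @param capacity_fraction Threshold fraction for
#'   [time_to_fraction_of_capacity()].
#' @return Named list of class `"summary_metrics"`.
#' @export
summarize_trajectory <- function(traj, variable = "T_I",
                                 auc_window = c(0, 10),
                                 capacity_fraction = 0.95) {
  stopifnot(inherits(traj, "trajectory"))
  span <- range(traj$times)
  auc_window <- c(max(auc_window[1L], span[1L]), min(auc_window[2L], span[2L]))
  pk <- traj_peak(traj, variable)
  tot <- traj$states[, "T_U"] + traj$states[, "T_I"]
  burden_at <- function(day) {
    if (day > span[2L]) return(NA_real_)
    stats::approx(traj$times, tot, xout = day)$y
  }
  structure(list(
    variable = variable,
    peak_value = pk$value,
    peak_time = pk$time,
    auc = traj_auc(traj, variable, auc_window),
    auc_window = auc_window,
    time_to_capacity = time_to_fraction_of_capacity(traj, capacity_fraction),
    capacity_fraction = capacity_fraction,
    cleared = is_cleared(traj),
    invaded_fraction_max = invaded_fraction_max(traj, "initial_tumor"),
    tumor_day15 = burden_at(15),
    tumor_day30 = burden_at(30),
    tumor_final = tot[length(tot)]
  ), class = "summary_metrics")
}

#' @export
print.summary_metrics <- function(x, ...) {
  cat(sprintf("<summary_metrics> focal variable %s\n", x$variable))
  cat(sprintf("  peak %.4g at day %.3g; AUC[%g,%g] = %.5g\n",
              x$peak_value, x$peak_time, x$auc_window[1L], x$auc_window[2L],
              x$auc))
  cat(sprintf("  time to %.0f%% capacity: %s; cleared: %s\n",
              100 * x$capacity_fraction,
              if (is.na(x$time_to_capacity)) "not reached"
              else sprintf("%.3g d", x$time_to_capacity),
              x$cleared))
  cat(sprintf("  max invaded fraction (of initial tumor): %.3g\n",
              x$invaded_fraction_max))
  invisible(x)
}
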