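# Stiff integration of the therapy model and closed-form limiting-case oracles.

#' Simulation settings
#'
#' @param t_end Simulation horizon in days (> 0). Default 30, the standard
#'   treatment window.
#' @param output_step Reporting grid spacing in days (> 0). The default 0.01
#'   day resolves sub-day invasion peaks (about seven hours post-injection).
#' @param rel_tol Relative local error tolerance of the integrator.
#' @param abs_tol Absolute tolerance; either a scalar or a named per-state
#'   vector. The default uses 1e-6 for the count states (CFU/cells) and 1e-9
#'   for the cytokine concentration, reflecting their different magnitudes.
#' @param negativity_policy `"clamp"` (default) reports tiny negative solver
#'   transients as 0 and aborts only on negativity beyond the solver's local
#'   error scale (`abs_tol + rel_tol * max|y|` per state); `"reject"` aborts
#'   on any negativity beyond `-abs_tol`.
#' @return List of class `"simulation_settings"`.
#' @export
simulation_settings <- function(t_end = 30, output_step = 0.01,
                                rel_tol = 1e-8, abs_tol = NULL,
                                negativity_policy = c("clamp", "reject")) {
  negativity_policy <- match.arg(negativity_policy)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (!is.finite(output_step) || output_step <= 0) {
    stop("output_step must be > 0", call. = FALSE)
  }
  if (!is.finite(rel_tol) || rel_tol <= 0) {
    stop("rel_tol must be > 0", call. = FALSE)
  }
  if (is.null(abs_tol)) {
    abs_tol <- c(S_B = 1e-6, S_T = 1e-6, T_U = 1e-6, T_I = 1e-6,
                 E_B = 1e-6, E_T = 1e-6, E_N = 1e-6, I_C = 1e-9)
  } else if (length(abs_tol) == 1L && is.null(names(abs_tol))) {
    abs_tol <- stats::setNames(rep(as.numeric(abs_tol), 8L), state_names())
  } else {
    abs_tol <- abs_tol[state_names()]
    if (anyNA(abs_tol)) stop("abs_tol must cover all states", call. = FALSE)
  }
  if (any(!is.finite(abs_tol)) || any(abs_tol <= 0)) {
    stop("abs_tol must be > 0", call. = FALSE)
  }
  structure(list(t_end = t_end, output_step = output_step,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 negativity_policy = negativity_policy),
            class = "simulation_settings")
}

#' Integrate the therapy model
#'
#' Integrates the eight-compartment system with a stiff-capable adaptive
#' method (`deSolve::lsoda`) and reports the solution on a uniform grid. If
#' the initial-condition vector carries parameter overrides (as produced by
#' [baseline_initial_conditions()] for hot tumors), they are applied to
#' `params` before integration.
#'
#' @param params Named parameter vector, see [baseline_parameters()].
#' @param ic Named initial-condition vector over [state_names()]; may carry a
#'   `"param_overrides"` attribute.
#' @param settings A [simulation_settings()] object.
#' @return Object of class `"trajectory"`: list with `times` (days, starting
#'   at 0), `states` (matrix, one row per time point, columns
#'   [state_names()]), `params` and `settings` as used, and `diagnostics`
#'   (integrator step statistics).
#' @export
#' @examples
#' traj <- simulate_therapy(
#'   baseline_parameters(),
#'   baseline_initial_conditions("intravenous", "cold", 1e6, 1e6),
#'   simulation_settings(t_end = 5, output_step = 0.1)
#' )
#' traj
simulate_therapy <- function(params, ic,
                             settings = simulation_settings()) {
  stopifnot(inherits(settings, "simulation_settings"))
  overrides <- attr(ic, "param_overrides")
  if (!is.null(overrides) && length(overrides) > 0) {
    params <- apply_overrides(params, ic, overrides)$params
  }
  validate_parameters(params)
  ic <- validate_state(ic, what = "initial condition")
  times <- seq(0, settings$t_end, by = settings$output_step)
  if (times[length(times)] < settings$t_end) {
    times <- c(times, settings$t_end)
  }
  sol <- suppressWarnings(
    deSolve::lsoda(y = ic, times = times, func = rhs_desolve,
                   parms = params,
                   rtol = settings$rel_tol, atol = settings$abs_tol,
                   maxsteps = 50000L)
  )
  istate <- attr(sol, "istate")
  if (is.null(istate) || istate[1L] < 0 || nrow(sol) < length(times)) {
    stop(sprintf("integration failed at t = %.6g days", sol[nrow(sol), 1L]),
         call. = FALSE)
  }
  states <- unname(sol[, -1L, drop = FALSE])
  colnames(states) <- state_names()
  if (any(!is.finite(states))) {
    stop("non-finite state values in solution", call. = FALSE)
  }
  # Negativity policy. The solver's local error scales as
  # rel_tol * |y| + abs_tol, so harmless negative transients can slightly
  # exceed abs_tol for large-magnitude states; "clamp" tolerates negatives
  # within that error scale (using each state's trajectory maximum),
  # "reject" only within abs_tol itself.
  floor_vec <- if (settings$negativity_policy == "clamp") {
    -(settings$abs_tol +
        settings$rel_tol * apply(abs(states), 2L, max))
  } else {
    -settings$abs_tol
  }
  floor_ <- matrix(rep(floor_vec, each = nrow(states)), nrow = nrow(states))
  too_neg <- states < floor_
  if (any(too_neg)) {
    idx <- which(too_neg, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "state %s is negative beyond tolerance (%.4g) at t = %.4g days",
      state_names()[idx[2L]], states[idx[1L], idx[2L]],
      sol[idx[1L], 1L]), call. = FALSE)
  }
  states[states < 0] <- 0
  structure(list(times = sol[, 1L], states = states,
                 params = params, settings = settings,
                 diagnostics = list(istate = istate)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over %.4g days (step %.4g)\n",
              length(x$times), max(x$times), x$settings$output_step))
  final <- x$states[nrow(x$states), ]
  cat("final state:\n")
  print(signif(final, 4))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Extract one state variable's time course
#'
#' @param traj A `"trajectory"`.
#' @param variable One of [state_names()].
#' @return Numeric vector aligned with `traj$times`.
#' @export
trajectory_variable <- function(traj, variable) {
  stopifnot(inherits(traj, "trajectory"))
  if (identical(variable, "T_total")) {
    return(traj$states[, "T_U"] + traj$states[, "T_I"])
  }
  if (!variable %in% state_names()) {
    stop("unknown state variable: ", variable,
         "; expected one of ", paste(state_names(), collapse = ", "),
         " or T_total", call. = FALSE)
  }
  traj$states[, variable]
}

#' Closed-form blood bacteria decay
#'
#' The blood compartment decouples from the rest of the system and decays
#' exponentially: `S_B(t) = S_B0 * exp(-k1 * t)`. Used as an independent
#' oracle for the numerical integrator.
#'
#' @param t Time(s) in days, >= 0.
#' @param S_B0 Injected bolus (CFU).
#' @param k1 Tumor infiltration rate (day^-1).
#' @return Blood bacterial count(s) at `t`.
#' @export
#' @examples
#' closed_form_blood(5, 1e6, 0.5)  # < 10% of the bolus remains
closed_form_blood <- function(t, S_B0, k1) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be non-negative and finite", call. = FALSE)
  }
  S_B0 * exp(-k1 * t)
}

#' Closed-form logistic tumor growth
#'
#' In the absence of bacteria and effector T cells the uninvaded tumor obeys
#' the logistic equation with carrying capacity `K = 1/b`:
#' `T(t) = K / (1 + (K/T0 - 1) * exp(-a t))`. Used as an independent oracle.
#'
#' @param t Time(s) in days, >= 0.
#' @param T0 Initial tumor cell count, > 0.
#' @param a Growth rate (day^-1).
#' @param b Inverse carrying capacity (cell^-1), > 0.
#' @return Tumor cell count(s) at `t`.
#' @export
closed_form_logistic <- function(t, T0, a, b) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be non-negative and finite", call. = FALSE)
  }
  if (!is.finite(T0) || T0 <= 0) stop("T0 must be > 0", call. = FALSE)
  if (!is.finite(b) || b <= 0) stop("b must be > 0", call. = FALSE)
  K <- 1 / b
  K / (1 + (K / T0 - 1) * exp(-a * t))
}
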