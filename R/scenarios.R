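# Declarative scenario engine: named baselines plus override sweeps, run
# side by side and summarized in tidy tables.

#' Define a simulation scenario
#'
#' A scenario is a named baseline treatment setting (route, immune state,
#' tumor size, dose) with optional parameter/initial-condition overrides and
#' an optional sweep: a named list of override sets that are simulated side
#' by side as arms. Override symbols are the parameter names
#' ([parameter_names()]) and the initial conditions written with a trailing
#' zero (`S_B0`, ..., `I_C0`).
#'
#' @param name Scenario identifier.
#' @param route,immune_state,tumor_size,dose Baseline setting, see
#'   [baseline_initial_conditions()].
#' @param overrides Named list of overrides applied to every arm.
#' @param sweep Optional named list; each element is a named list of
#'   overrides defining one arm. `NULL` means a single baseline arm.
#' @param horizon Simulation horizon in days.
#' @param focal_variable State variable summarized per arm (default `"T_I"`).
#' @param auc_window AUC window passed to [summarize_trajectory()].
#' @return List of class `"scenario_spec"`.
#' @export
#' @examples
#' scenario_spec("k1_sweep",
#'   sweep = list(`k1=0.05` = list(k1 = 0.05),
#'                `k1=0.5`  = list(k1 = 0.5),
#'                `k1=5`    = list(k1 = 5)))
scenario_spec <- function(name,
                          route = "intravenous", immune_state = "cold",
                          tumor_size = 1e6, dose = 1e6,
                          overrides = list(), sweep = NULL,
                          horizon = 30, focal_variable = "T_I",
                          auc_window = c(0, 10)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("name must be a non-empty string", call. = FALSE)
  }
  if (!is.null(sweep)) {
    if (!is.list(sweep) || length(sweep) == 0L) {
      stop("sweep must be NULL or a non-empty named list", call. = FALSE)
    }
    if (is.null(names(sweep)) || any(names(sweep) == "")) {
      stop("every sweep arm must be named", call. = FALSE)
    }
  }
  structure(list(name = name, route = route, immune_state = immune_state,
                 tumor_size = tumor_size, dose = dose,
                 overrides = overrides, sweep = sweep, horizon = horizon,
                 focal_variable = focal_variable, auc_window = auc_window),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: %s %s tumor, T_U0 = %g cells, dose %g CFU\n",
              x$name, x$immune_state, x$route, x$tumor_size, x$dose))
  if (length(x$overrides)) {
    cat("  overrides:", paste(names(x$overrides), unlist(x$overrides),
                              sep = " = ", collapse = ", "), "\n")
  }
  cat(sprintf("  arms: %s; horizon %g days\n",
              if (is.null(x$sweep)) "baseline only"
              else paste(names(x$sweep), collapse = ", "),
              x$horizon))
  invisible(x)
}

#' Run a scenario
#'
#' Resolves every arm's parameters and initial conditions, validates all
#' override symbols before any simulation runs, and simulates each arm with
#' identical settings. Arms are returned in specification order.
#'
#' @param spec A [scenario_spec()].
#' @param settings A [simulation_settings()]; its `t_end` is replaced by the
#'   scenario horizon.
#' @param base_params Parameter set the scenario starts from.
#' @return Object of class `"scenario_result"`: list with `spec`, `arms` (per
#'   arm: `trajectory`, `metrics`, resolved `params`/`ic`) and `table`, a
#'   tidy data frame (one row per arm x metric).
#' @export
run_scenario <- function(spec, settings = simulation_settings(),
                         base_params = baseline_parameters()) {
  stopifnot(inherits(spec, "scenario_spec"))
  settings$t_end <- spec$horizon
  arms <- if (is.null(spec$sweep)) list(baseline = list()) else spec$sweep
  base_ic <- baseline_initial_conditions(spec$route, spec$immune_state,
                                         spec$tumor_size, spec$dose)
  hot_overrides <- attr(base_ic, "param_overrides")
  attr(base_ic, "param_overrides") <- NULL
  # Resolve (and thereby validate) every arm before simulating any.
  resolved <- lapply(arms, function(arm_overrides) {
    r <- apply_overrides(base_params, base_ic, hot_overrides)
    r <- apply_overrides(r$params, r$ic, spec$overrides)
    apply_overrides(r$params, r$ic, arm_overrides)
  })
  results <- lapply(resolved, function(r) {
    traj <- simulate_therapy(r$params, r$ic, settings)
    list(trajectory = traj,
         metrics = summarize_trajectory(traj, spec$focal_variable,
                                        spec$auc_window),
         params = r$params, ic = r$ic)
  })
  tab <- do.call(rbind, lapply(names(results), function(arm) {
    m <- results[[arm]]$metrics
    vu <- state_units()[[spec$focal_variable]]
    data.frame(
      arm = arm,
      metric = c("peak_value", "peak_time", "auc", "time_to_capacity",
                 "cleared", "invaded_fraction_max", "tumor_day15",
                 "tumor_day30"),
      value = c(m$peak_value, m$peak_time, m$auc, m$time_to_capacity,
                as.numeric(m$cleared), m$invaded_fraction_max,
                m$tumor_day15, m$tumor_day30),
      unit = c(vu, "day", paste0(vu, "*day"), "day", "flag", "1",
               "cells", "cells"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  structure(list(spec = spec, arms = results, table = tab,
                 settings = settings, base_params = base_params),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (%d arm%s)\n", x$spec$name,
              length(x$arms), if (length(x$arms) == 1L) "" else "s"))
  wide <- stats::reshape(x$table[, c("arm", "metric", "value")],
                         idvar = "arm", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Catalog of the standard in-silico experiments
#'
#' Returns the named scenarios explored with this model:
#' \describe{
#'   \item{route_comparison}{Intravenous vs intratumoral delivery of a 1e6
#'     CFU bolus into a cold 1e6-cell tumor.}
#'   \item{hot_vs_cold_untreated / hot_vs_cold_treated}{Cold
#'     (`I_C0 = 10`, baseline `l2`) vs hot (`I_C0 = 100`, `l2 = 0`)
#'     microenvironments without and with a 1e6 CFU intravenous bolus.}
#'   \item{dose_by_size}{Grid of doses \{0, 1e2, 1e4, 1e6\} CFU by initial
#'     tumor sizes \{1e5, 1e6, 1e7\} cells.}
#'   \item{k1_sweep}{Tumor infiltration rate 0.05 / 0.5 / 5 day^-1.}
#'   \item{k2_sweep}{Cell invasion rate at one hundredth, one, and one
#'     hundred times the baseline 2.97e-6 cell^-1 day^-1.}
#'   \item{k3_sweep}{Bacterial cytotoxicity 0.32 / 3.2 / 32 day^-1.}
#'   \item{l1_sweep}{Cytokine production 0.297 / 2.97 / 29.7
#'     ng mL^-1 cell^-1 day^-1.}
#'   \item{no_activation_dose_sweep}{T cell activation knocked out
#'     (`t1 = t2 = 0`) across doses \{0, 1e2, 1e4, 1e6\} CFU.}
#'   \item{knockout_EB / knockout_ET}{Single-pool activation knockouts
#'     (`t1 = 0` removes bacteria-specific T cells; `t2 = 0` removes
#'     pan-tumor T cells).}
#'   \item{d3_sweep}{Checkpoint-blockade mimic: exhaustion rate log-spaced
#'     over five arms from 0.105 down to 0.001 day^-1.}
#' }
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
scenario_catalog <- function() {
  arm_list <- function(symbol, values, labels = NULL) {
    labs <- if (is.null(labels)) paste0(symbol, "=", format(values)) else labels
    stats::setNames(lapply(values, function(v) {
      stats::setNames(list(v), symbol)
    }), labs)
  }
  dose_grid <- function() {
    doses <- c(0, 1e2, 1e4, 1e6)
    sizes <- c(1e5, 1e6, 1e7)
    arms <- list()
    for (sz in sizes) for (d in doses) {
      arms[[sprintf("size=%.0e_dose=%.0e", sz, d)]] <-
        list(T_U0 = sz, S_B0 = d)
    }
    arms
  }
  d3_values <- exp(seq(log(0.105), log(0.001), length.out = 5))
  list(
    route_comparison = scenario_spec(
      "route_comparison",
      sweep = list(intravenous  = list(S_B0 = 1e6, S_T0 = 0),
                   intratumoral = list(S_B0 = 0, S_T0 = 1e6))),
    hot_vs_cold_untreated = scenario_spec(
      "hot_vs_cold_untreated", dose = 0,
      sweep = list(cold = list(),
                   hot = list(I_C0 = 100, l2 = 0))),
    hot_vs_cold_treated = scenario_spec(
      "hot_vs_cold_treated",
      sweep = list(cold = list(),
                   hot = list(I_C0 = 100, l2 = 0))),
    dose_by_size = scenario_spec("dose_by_size", sweep = dose_grid()),
    k1_sweep = scenario_spec("k1_sweep",
                             sweep = arm_list("k1", c(0.05, 0.5, 5))),
    k2_sweep = scenario_spec("k2_sweep",
                             sweep = arm_list("k2",
                                              c(2.97e-8, 2.97e-6, 2.97e-4))),
    k3_sweep = scenario_spec("k3_sweep",
                             sweep = arm_list("k3", c(0.32, 3.2, 32))),
    l1_sweep = scenario_spec("l1_sweep",
                             sweep = arm_list("l1", c(0.297, 2.97, 29.7))),
    no_activation_dose_sweep = scenario_spec(
      "no_activation_dose_sweep",
      overrides = list(t1 = 0, t2 = 0),
      sweep = arm_list("S_B0", c(0, 1e2, 1e4, 1e6),
                       labels = c("dose=0", "dose=1e2", "dose=1e4",
                                  "dose=1e6"))),
    knockout_EB = scenario_spec("knockout_EB", overrides = list(t1 = 0)),
    knockout_ET = scenario_spec("knockout_ET", overrides = list(t2 = 0)),
    d3_sweep = scenario_spec(
      "d3_sweep",
      sweep = arm_list("d3", d3_values,
                       labels = sprintf("d3=%.4g", d3_values)))
  )
}
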