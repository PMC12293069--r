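# Parameter and initial-condition constructors for the Salmonella therapy model.

#' State variable names of the therapy model
#'
#' The model tracks eight compartments: `S_B`, bacteria in the blood (CFU);
#' `S_T`, extracellular intratumoral bacteria (CFU); `T_U`, uninvaded cancer
#' cells (cells); `T_I`, bacterially invaded cancer cells (cells); `E_B`,
#' bacterial-antigen-specific effector T cells (cells); `E_T`, pan-tumor
#' effector T cells (cells); `E_N`, naive T cells (cells); and `I_C`, the
#' inflammatory cytokine concentration (ng/mL).
#'
#' @return Character vector of the eight state names, in model order.
#' @export
#' @examples
#' state_names()
state_names <- function() {
  c("S_B", "S_T", "T_U", "T_I", "E_B", "E_T", "E_N", "I_C")
}

#' Units of the state variables
#'
#' @return Named character vector mapping each state name to its unit.
#' @export
state_units <- function() {
  c(S_B = "CFU", S_T = "CFU", T_U = "cells", T_I = "cells",
    E_B = "cells", E_T = "cells", E_N = "cells", I_C = "ng/mL")
}

#' Parameter names of the therapy model
#'
#' The 19 rate and saturation constants of the model, plus `d0`, an optional
#' extra first-order clearance of blood bacteria that do not reach the tumor
#' (an extrapolation beyond the core model; its default is 0 so the baseline
#' dynamics are unaffected).
#'
#' @return Character vector of parameter names.
#' @export
parameter_names <- function() {
  c("k1", "k2", "k3", "d1", "a", "b", "s1", "s2", "h1",
    "t1", "t2", "h2", "h3", "d2", "d3", "i", "l1", "l2", "g1", "d0")
}

#' Literature baseline parameter set
#'
#' Returns the default parameterization of the model: bacterial tumor
#' infiltration `k1` (day^-1), cell-invasion rate `k2` (cell^-1 day^-1),
#' bacteria-mediated tumor cell death `k3` (day^-1), extracellular bacterial
#' clearance `d1` (day^-1), tumor growth rate `a` (day^-1), inverse carrying
#' capacity `b` (cell^-1; the carrying capacity is `1/b`, about 9.8e8 cells),
#' T cell killing rates `s1` and `s2` (day^-1), killing half-max `h1` (cells),
#' activation rates `t1` and `t2` (day^-1) with half-maxes `h2` and `h3`
#' (cells), T cell loss after tumor contact `d2` (cell^-1 day^-1), T cell
#' exhaustion rate `d3` (day^-1), naive T cell influx `i` (cells day^-1),
#' cytokine production per bacterium `l1` (ng mL^-1 cell^-1 day^-1), cytokine
#' degradation `l2` (day^-1), and cytokine activation half-max `g1` (ng/mL).
#'
#' `d1` is implemented as a first-order rate constant acting on `S_T`, which
#' is how it enters the equations. The cytokine production rate `l1` defaults
#' to 2.97, the middle value of the threefold production sweep and the value
#' consistent with the baseline trajectories; it sits inside the reported
#' plausible range 2.88-5.76 and is freely overridable. `l2` uses the
#' four-digit value 0.5137 day^-1.
#'
#' @param l1 Cytokine production rate to use (ng mL^-1 cell^-1 day^-1).
#' @param d0 Extra blood clearance rate (day^-1) of bacteria that never
#'   reach the tumor; 0 disables this extension.
#' @return Named numeric vector over [parameter_names()].
#' @export
#' @examples
#' p <- baseline_parameters()
#' 1 / p[["b"]]  # carrying capacity, cells
baseline_parameters <- function(l1 = 2.97, d0 = 0) {
  p <- c(k1 = 0.5, k2 = 2.97e-6, k3 = 3.20, d1 = 0.001,
         a = 0.43, b = 1.02e-9, s1 = 2.87, s2 = 2.13, h1 = 5e3,
         t1 = 1.50, t2 = 1.23, h2 = 2.50e3, h3 = 2.50e3,
         d2 = 3.03e-10, d3 = 0.11, i = 90,
         l1 = l1, l2 = 0.5137, g1 = 120, d0 = d0)
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks that all parameters are present, finite and non-negative, and that
#' the saturation constants `b`, `h1`, `h2`, `h3` and `g1` are strictly
#' positive.
#'
#' @param params Named numeric vector over [parameter_names()].
#' @return The validated vector, invisibly.
#' @export
validate_parameters <- function(params) {
  required <- parameter_names()
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(params), required)
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  vals <- params[required]
  bad <- required[!is.finite(vals)]
  if (length(bad) > 0) {
    stop("non-finite parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  neg <- required[vals < 0]
  if (length(neg) > 0) {
    stop("negative parameter(s): ", paste(neg, collapse = ", "), call. = FALSE)
  }
  strict <- c("b", "h1", "h2", "h3", "g1")
  zero <- strict[params[strict] <= 0]
  if (length(zero) > 0) {
    stop("parameter(s) must be strictly positive: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  invisible(params)
}

#' Validate a state or initial-condition vector
#'
#' @param state Named numeric vector over [state_names()].
#' @param what Label used in error messages.
#' @return The validated vector (reordered to model order), invisibly.
#' @export
validate_state <- function(state, what = "state") {
  required <- state_names()
  missing <- setdiff(required, names(state))
  if (length(missing) > 0) {
    stop("missing ", what, " component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  state <- state[required]
  bad <- required[!is.finite(state)]
  if (length(bad) > 0) {
    stop("non-finite ", what, " component(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  neg <- required[state < 0]
  if (length(neg) > 0) {
    stop("negative ", what, " component(s): ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  invisible(state)
}

#' Baseline initial conditions for a treatment setting
#'
#' Builds the state vector at the moment of bacterial injection (t = 0). An
#' intravenous bolus places the dose in the blood compartment (`S_B`); an
#' intratumoral injection places it directly in the extracellular tumor
#' compartment (`S_T`), bypassing infiltration. The immune state sets the
#' initial cytokine level: a cold (immunosuppressed) tumor starts at
#' `I_C = 10` ng/mL with cytokines degrading at the baseline rate, while a
#' hot (immune-active) tumor starts at `I_C = 100` ng/mL with no cytokine
#' degradation (`l2 = 0`), representing a sustained inflammatory
#' microenvironment. The hot setting is communicated as a parameter override
#' attached to the returned vector (attribute `"param_overrides"`), which
#' [simulate_therapy()] applies automatically.
#'
#' All settings start with `E_N = 100` naive T cells and no activated T cells
#' or invaded cancer cells.
#'
#' @param route `"intravenous"` or `"intratumoral"`.
#' @param immune_state `"cold"` or `"hot"`.
#' @param tumor_size Initial uninvaded tumor cell count (cells), > 0.
#' @param dose Injected bacterial bolus (CFU), >= 0.
#' @return Named numeric vector over [state_names()], with attribute
#'   `"param_overrides"` (a named list, possibly empty).
#' @export
#' @examples
#' baseline_initial_conditions("intravenous", "cold", 1e6, 1e6)
baseline_initial_conditions <- function(route = c("intravenous", "intratumoral"),
                                        immune_state = c("cold", "hot"),
                                        tumor_size = 1e6, dose = 1e6) {
  route <- match.arg(route)
  immune_state <- match.arg(immune_state)
  if (!is.finite(tumor_size) || tumor_size <= 0) {
    stop("tumor_size must be a positive, finite cell count", call. = FALSE)
  }
  if (!is.finite(dose) || dose < 0) {
    stop("dose must be a non-negative, finite CFU count", call. = FALSE)
  }
  ic <- c(S_B = 0, S_T = 0, T_U = tumor_size, T_I = 0,
          E_B = 0, E_T = 0, E_N = 100,
          I_C = if (immune_state == "cold") 10 else 100)
  if (route == "intravenous") ic[["S_B"]] <- dose else ic[["S_T"]] <- dose
  overrides <- if (immune_state == "hot") list(l2 = 0) else list()
  attr(ic, "param_overrides") <- overrides
  ic
}

#' Apply override symbols to a parameter set and initial conditions
#'
#' Override names ending in `"0"` (e.g. `S_B0`, `I_C0`) address initial
#' conditions; all other names address parameters. Unknown symbols raise an
#' error before anything is modified.
#'
#' @param params Named parameter vector.
#' @param ic Named initial-condition vector.
#' @param overrides Named list or vector of numeric override values.
#' @return List with elements `params` and `ic`.
#' @export
apply_overrides <- function(params, ic, overrides) {
  overrides <- as.list(overrides)
  if (length(overrides) == 0) return(list(params = params, ic = ic))
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("all overrides must be named", call. = FALSE)
  }
  ic_keys <- paste0(state_names(), "0")
  valid <- c(parameter_names(), ic_keys)
  unknown <- setdiff(nms, valid)
  if (length(unknown) > 0) {
    stop("unknown override symbol(s): ", paste(unknown, collapse = ", "),
         "; valid symbols are the parameters (",
         paste(parameter_names(), collapse = ", "),
         ") and initial conditions (", paste(ic_keys, collapse = ", "), ")",
         call. = FALSE)
  }
  for (nm in nms) {
    val <- as.numeric(overrides[[nm]])
    if (nm %in% ic_keys) {
      ic[[sub("0$", "", nm)]] <- val
    } else {
      params[[nm]] <- val
    }
  }
  list(params = params, ic = ic)
}
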