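# Right-hand side of the eight-compartment tumor/immune/bacteria ODE system.

#' Evaluate the model right-hand side
#'
#' Computes the instantaneous per-day rate of change of each state variable:
#'
#' \describe{
#'   \item{S_B}{`-(k1 + d0) * S_B` — blood bacteria infiltrate the tumor at
#'     rate `k1` (plus optional non-tumor clearance `d0`, default 0).}
#'   \item{S_T}{`k1*S_B - k2*S_T*T_U - d1*S_T` — infiltration in, cell
#'     invasion and extracellular death out.}
#'   \item{T_U}{`a*T_U*(1 - b*(T_U + T_I)) - k2*S_T*T_U -
#'     s1*T_U*E_T/(h1 + E_T)` — logistic growth against the shared carrying
#'     capacity `1/b`, loss to invasion, and saturating killing by pan-tumor
#'     T cells.}
#'   \item{T_I}{`k2*S_T*T_U - k3*T_I - s1*T_I*E_T/(h1 + E_T) -
#'     s2*T_I*E_B/(h1 + E_B)` — invaded cells do not proliferate; they die
#'     from intracellular bacteria and both T cell pools.}
#'   \item{E_B}{`t1*E_N*T_I/(h2 + T_I)*I_C/(g1 + I_C) - d2*E_B*T_I - d3*E_B`
#'     — memory reactivation against invaded cells, gated by cytokines.}
#'   \item{E_T}{`t2*E_N*(T_U + T_I)/(h3 + T_U + T_I)*I_C/(g1 + I_C) -
#'     d2*E_T*(T_U + T_I) - d3*E_T` — naive activation against all tumor
#'     cells, gated by cytokines.}
#'   \item{E_N}{`i - t1*E_N*T_I/(h2 + T_I) -
#'     t2*E_N*(T_U + T_I)/(h3 + T_U + T_I)` — constant influx minus both
#'     activation drains.}
#'   \item{I_C}{`l1*S_T - l2*I_C` — production by extracellular intratumoral
#'     bacteria, first-order degradation.}
#' }
#'
#' @param state Named numeric vector over [state_names()]; must be finite and
#'   non-negative.
#' @param params Named numeric vector over [parameter_names()].
#' @return Named numeric vector of derivatives (per-day rates), one per state.
#' @export
#' @examples
#' evaluate_rhs(
#'   c(S_B = 1e6, S_T = 0, T_U = 1e6, T_I = 0,
#'     E_B = 0, E_T = 0, E_N = 100, I_C = 10),
#'   baseline_parameters()
#' )
evaluate_rhs <- function(state, params) {
  state <- validate_state(state)
  validate_parameters(params)
  d <- rhs_raw(state, params)
  names(d) <- state_names()
  d
}

# Unchecked RHS shared by evaluate_rhs() and the integrator. `state` must be
# in model order. Negative transients from the stiff solver are tolerated
# here; the reporting layer applies the negativity policy.
rhs_raw <- function(state, params) {
  S_B <- state[[1L]]; S_T <- state[[2L]]
  T_U <- state[[3L]]; T_I <- state[[4L]]
  E_B <- state[[5L]]; E_T <- state[[6L]]
  E_N <- state[[7L]]; I_C <- state[[8L]]
  p <- params
  T_tot <- T_U + T_I
  kill_ET <- p[["s1"]] * E_T / (p[["h1"]] + E_T)
  kill_EB <- p[["s2"]] * E_B / (p[["h1"]] + E_B)
  cyto_gate <- I_C / (p[["g1"]] + I_C)
  act_B <- p[["t1"]] * E_N * T_I / (p[["h2"]] + T_I)
  act_T <- p[["t2"]] * E_N * T_tot / (p[["h3"]] + T_tot)
  c(
    -(p[["k1"]] + p[["d0"]]) * S_B,
    p[["k1"]] * S_B - p[["k2"]] * S_T * T_U - p[["d1"]] * S_T,
    p[["a"]] * T_U * (1 - p[["b"]] * T_tot) - p[["k2"]] * S_T * T_U -
      T_U * kill_ET,
    p[["k2"]] * S_T * T_U - p[["k3"]] * T_I - T_I * kill_ET - T_I * kill_EB,
    act_B * cyto_gate - p[["d2"]] * E_B * T_I - p[["d3"]] * E_B,
    act_T * cyto_gate - p[["d2"]] * E_T * T_tot - p[["d3"]] * E_T,
    p[["i"]] - act_B - act_T,
    p[["l1"]] * S_T - p[["l2"]] * I_C
  )
}

# deSolve-facing wrapper.
rhs_desolve <- function(t, y, parms) {
  list(rhs_raw(y, parms))
}
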