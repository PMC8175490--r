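#' Rate equations of the PAC biotransformation model
#'
#' The pointwise rate laws of the six-state model. `pac_rate()` is the
#' carboligation rate: a Hill-type benzaldehyde binding factor
#' `K_b B^h / (1 + K_b B^h)` times a Michaelis-Menten pyruvate factor
#' `A / (K_ma + A)` times the relative enzyme activity `E`, scaled by
#' `V_p`. `byproduct_rates()` gives acetaldehyde (`dQ = V_q A E -
#' V_r A Q E`) and acetoin (`dR = V_r A Q E`) formation.
#' `substrate_rates()` maps product/by-product rates onto substrate
#' consumption by stoichiometry: `dA = -dP - dQ - 2 dR` (one pyruvate per
#' PAC or acetaldehyde, two per acetoin counting its acetaldehyde
#' precursor) and `dB = -dP`. `enzyme_rate()` is the deactivation law
#' `-(k_d1 + k_d2 B) E + k_a Ph_b` once the initial lag `t_lag` has
#' passed, and 0 before.
#'
#' @param state Named numeric vector (or list) with components `P`, `A`,
#'   `B`, `Q`, `R`, `E` as needed by the rate; concentrations in mM,
#'   `E` in % relative activity.
#' @param params A [kinetic_parameters()] object.
#' @return `pac_rate()`: a single rate in mM min^-1.
#' @export
#' @examples
#' p <- pac_parameters_optimized()
#' pac_rate(c(A = 116, B = 100, E = 114), p)
pac_rate <- function(state, params) {
  params <- as_kinetic_parameters(params)
  s <- unlist(state)
  check_finite(s, "state")
  A <- s[["A"]]; B <- s[["B"]]; E <- s[["E"]]
  kb <- if (B > 0) params[["K_b"]] * B^params[["h"]] else 0
  params[["V_p"]] * (kb / (1 + kb)) * (A / (params[["K_ma"]] + A)) * E
}

#' @rdname pac_rate
#' @return `byproduct_rates()`: a named numeric vector with `dQ` and
#'   `dR` in mM min^-1.
#' @export
byproduct_rates <- function(state, params) {
  params <- as_kinetic_parameters(params)
  s <- unlist(state)
  check_finite(s, "state")
  A <- s[["A"]]; Q <- s[["Q"]]; E <- s[["E"]]
  dR <- params[["V_r"]] * A * Q * E
  dQ <- params[["V_q"]] * A * E - dR
  c(dQ = dQ, dR = dR)
}

#' @rdname pac_rate
#' @param dP,dQ,dR Formation rates of PAC, acetaldehyde and acetoin
#'   (mM min^-1).
#' @return `substrate_rates()`: a named numeric vector with `dA` and
#'   `dB` in mM min^-1.
#' @export
substrate_rates <- function(dP, dQ, dR) {
  check_finite(c(dP, dQ, dR), "rates")
  c(dA = -dP - dQ - 2 * dR, dB = -dP)
}

#' @rdname pac_rate
#' @param conditions A [reaction_conditions()] object (supplies the
#'   phosphate buffer concentration).
#' @param t Elapsed reaction time in minutes.
#' @return `enzyme_rate()`: the rate of change of relative enzyme
#'   activity in % min^-1.
#' @export
enzyme_rate <- function(state, params, conditions, t) {
  params <- as_kinetic_parameters(params)
  stopifnot(inherits(conditions, "reaction_conditions"))
  check_scalar(t, "t"); check_finite(t, "t")
  if (t < 0) abort("`t` must be >= 0",
                   class = "packinetics_invalid_argument")
  if (t < params[["t_lag"]]) return(0)
  s <- unlist(state)
  check_finite(s, "state")
  B <- s[["B"]]; E <- s[["E"]]
  -(params[["k_d1"]] + params[["k_d2"]] * B) * E +
    params[["k_a"]] * conditions$Ph_b
}

#' Full state derivative of the PAC biotransformation model
#'
#' Assembles the six rate equations at one state, in the order
#' `P, A, B, Q, R, E`. Substrate consumption uses the product and
#' by-product rates evaluated at the same state, so the linear
#' stoichiometric identities `dA + dP + dQ + 2 dR = 0` and `dB + dP = 0`
#' hold exactly.
#'
#' @inheritParams enzyme_rate
#' @return A named numeric vector of the six time derivatives.
#' @export
pac_derivatives <- function(t, state, params, conditions) {
  params <- as_kinetic_parameters(params)
  s <- unlist(state)[species_codes()]
  dP <- pac_rate(s, params)
  bp <- byproduct_rates(s, params)
  su <- substrate_rates(dP, bp[["dQ"]], bp[["dR"]])
  dE <- enzyme_rate(s, params, conditions, t)
  c(P = dP, A = su[["dA"]], B = su[["dB"]],
    Q = bp[["dQ"]], R = bp[["dR"]], E = dE)
}
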