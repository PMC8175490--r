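#' Summary metrics of a PAC profile
#'
#' Computes the batch summary quantities from a sampled PAC time
#' course: the maximum PAC concentration `P_max` (earliest sampling
#' time attaining it), the maximum PAC formation rate `r_Pmax =
#' max_{t>0} P(t)/t`, the reaction time (`P_max / r_Pmax` rounded to
#' the nearest sampling interval), and the molar yields on benzaldehyde
#' and pyruvate at the time of `P_max`:
#' `Y_Pmax/B = P_max / (B0 - B(t_Pmax))` and
#' `Y_Pmax/A = P_max / (A0 - A(t_Pmax))`.
#'
#' @param profile A [pac_profile()] or `pac_trajectory` (sampled
#'   internally).
#' @param interval Sampling interval for the reaction-time rounding,
#'   min; defaults to the profile's own interval.
#' @return A one-row tibble with columns `P_max`, `t_Pmax`, `r_Pmax`,
#'   `reaction_time`, `Y_Pmax_B`, `Y_Pmax_A`.
#' @export
#' @examples
#' traj <- simulate_pac(pac_parameters_optimized(),
#'                      pac_study_conditions("100/120"))
#' summarize_profile(traj)
summarize_profile <- function(profile, interval = NULL) {
  if (inherits(profile, "pac_trajectory")) {
    cond <- attr(profile, "conditions")
    interval <- interval %||% cond$sampling_interval
    df <- sampled_states(profile)
  } else if (inherits(profile, "pac_profile")) {
    cond <- profile_conditions(profile)
    interval <- interval %||% cond$sampling_interval
    df <- as_tibble(profile)
  } else {
    abort("`profile` must be a pac_profile or pac_trajectory",
          class = "packinetics_invalid_argument")
  }
  t <- df$time_min
  if (length(t) < 3 || t[1] != 0) {
    abort("profile must include t = 0 and at least two later sampling times",
          class = "packinetics_invalid_argument")
  }
  P <- df$pac_mM; A <- df$pyruvate_mM; B <- df$benzaldehyde_mM
  i_max <- which.max(P)          # earliest index attaining the maximum
  P_max <- P[i_max]
  rates <- P[-1] / t[-1]
  r_Pmax <- max(rates)
  dB <- B[1] - B[i_max]
  dA <- A[1] - A[i_max]
  if (P_max > 0 && (dB <= 0 || dA <= 0)) {
    abort("yields undefined: no substrate consumption at the time of P_max",
          class = "packinetics_undefined_yield")
  }
  Y_B <- if (P_max > 0) P_max / dB else 0
  Y_A <- if (P_max > 0) P_max / dA else 0
  if (Y_B > 1 || Y_A > 1) {
    inform(sprintf("molar yield above 1 (Y_B = %.3f, Y_A = %.3f)", Y_B, Y_A),
           class = "packinetics_log")
  }
  tibble(P_max = P_max, t_Pmax = t[i_max], r_Pmax = r_Pmax,
         reaction_time = reaction_time(P_max, r_Pmax, interval),
         Y_Pmax_B = Y_B, Y_Pmax_A = Y_A)
}

#' Reaction time from maximum PAC level and formation rate
#'
#' The reaction time attaining `P_max` is `P_max / r_Pmax` rounded to
#' the nearest multiple of the sampling interval, with exact midpoints
#' rounded up.
#'
#' @param P_max Maximum PAC concentration, mM.
#' @param r_Pmax Maximum PAC formation rate, mM min^-1.
#' @param interval Sampling interval, min (study value 30).
#' @return Reaction time in minutes.
#' @export
#' @examples
#' reaction_time(25.8, 0.143, 30)  # 180.42 min rounds to 180
reaction_time <- function(P_max, r_Pmax, interval = 30) {
  check_nonneg(P_max, "P_max"); check_finite(r_Pmax, "r_Pmax")
  if (r_Pmax <= 0) {
    abort("`r_Pmax` must be > 0", class = "packinetics_invalid_argument")
  }
  if (interval <= 0) {
    abort("`interval` must be > 0", class = "packinetics_invalid_argument")
  }
  raw <- P_max / r_Pmax
  # nearest multiple, half-up
  floor(raw / interval + 0.5) * interval
}
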