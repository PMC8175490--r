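#' Residual sum of squares between observed and simulated profiles
#'
#' Computes the per-species residual sums of squares between the
#' replicate means of an observed profile and a simulated trajectory
#' sampled at the same times, and their total. Residuals are unweighted
#' squared differences, so concentration species contribute in squared
#' mM and the enzyme profile in squared percentage points.
#'
#' The total `RSS_T` sums the pyruvate, benzaldehyde, acetaldehyde,
#' acetoin and enzyme components and, by default, also the PAC
#' component. Set `include_pac = FALSE` to reproduce the five-term
#' literal form of the published objective (its prose description
#' includes product formation, which is the default here).
#'
#' @param observed A [pac_profile()].
#' @param simulated A `pac_trajectory` from [simulate_pac()] (it is
#'   sampled internally), or a data frame of sampled states with the
#'   same columns and times as the observations.
#' @param include_pac Include the PAC residuals in `RSS_T`? Default
#'   `TRUE`.
#' @return A one-row tibble with columns `RSS_P`, `RSS_A`, `RSS_B`,
#'   `RSS_Q`, `RSS_R`, `RSS_E` and `RSS_T`, carrying the `include_pac`
#'   choice as attribute.
#' @export
rss_breakdown <- function(observed, simulated, include_pac = TRUE) {
  stopifnot(inherits(observed, "pac_profile"))
  sim <- if (inherits(simulated, "pac_trajectory")) {
    sampled_states(simulated)
  } else {
    as_tibble(simulated)
  }
  if (nrow(sim) != nrow(observed) ||
      any(abs(sim$time_min - observed$time_min) > 1e-9)) {
    abort("simulated sampling times do not match the observed times",
          class = "packinetics_alignment_error")
  }
  obs_m <- profile_matrix(observed)
  cols <- species_columns()
  sim_m <- as.matrix(as.data.frame(sim)[, cols])
  comps <- colSums((obs_m - sim_m)^2)
  names(comps) <- species_codes()
  total <- sum(comps[c("A", "B", "Q", "R", "E")]) +
    if (include_pac) comps[["P"]] else 0
  out <- tibble(RSS_P = comps[["P"]], RSS_A = comps[["A"]],
                RSS_B = comps[["B"]], RSS_Q = comps[["Q"]],
                RSS_R = comps[["R"]], RSS_E = comps[["E"]],
                RSS_T = total)
  attr(out, "include_pac") <- include_pac
  out
}

#' Total sum of squares of an observed profile
#'
#' Per-species total sum of squares about each species' own mean,
#' summed over species; the denominator of the coefficient of
#' determination.
#'
#' @inheritParams rss_breakdown
#' @return A single number (squared mM / squared % units, summed).
#' @export
total_sum_squares <- function(observed, include_pac = TRUE) {
  obs_m <- profile_matrix(observed)
  keep <- species_codes()
  if (!include_pac) keep <- setdiff(keep, "P")
  sum(vapply(keep, function(s) {
    x <- obs_m[, s]
    sum((x - mean(x))^2)
  }, numeric(1)))
}

#' Fit statistics: degrees of freedom, mean squared error, R-squared
#'
#' Converts per-profile residual sums of squares into the study's fit
#' statistics. Each profile contributes `n_obs` regressed data points
#' (eight sampling times of six measured quantities = 48 by default)
#' and the model has `n_params` constants (10), so the per-profile
#' degrees of freedom are `n_obs - n_params` (= 38) and `MSE =
#' RSS_T / DOF`. Combined statistics over several profiles are the sums
#' of the per-profile values (both RSS and MSE), matching the published
#' convention. The coefficient of determination is `R2 = 1 - RSS_T /
#' TSS_T` with the total sum of squares taken about each species' own
#' mean.
#'
#' @param rss Numeric vector of per-profile total residual sums of
#'   squares, or a list of [rss_breakdown()] results.
#' @param n_obs Observations per profile (default 48).
#' @param n_params Number of fitted model constants (default 10).
#' @param tss Optional numeric vector of per-profile total sums of
#'   squares (from [total_sum_squares()]); enables the `R2` column.
#' @param labels Optional profile labels.
#' @return A tibble with one row per profile plus, when there are
#'   several profiles, a `"combined"` row; columns `profile`, `RSS_T`,
#'   `DOF`, `MSE` and (when `tss` is given) `R2`.
#' @export
#' @examples
#' fit_statistics(662)              # validation profile: MSE 17.4
#' fit_statistics(c(936, 2526))     # fitted pairs: combined 3462, 91.1
fit_statistics <- function(rss, n_obs = 48, n_params = 10, tss = NULL,
                           labels = NULL) {
  if (is.list(rss) && !is.data.frame(rss)) {
    rss <- vapply(rss, function(b) b$RSS_T[1], numeric(1))
  } else if (is.data.frame(rss)) {
    rss <- rss$RSS_T
  }
  check_nonneg(rss, "rss")
  dof <- n_obs - n_params
  if (dof <= 0) {
    abort("degrees of freedom must be positive (n_obs > n_params)",
          class = "packinetics_config_error")
  }
  n <- length(rss)
  labels <- labels %||% paste0("profile_", seq_len(n))
  out <- tibble(profile = labels, RSS_T = rss, DOF = rep(dof, n),
                MSE = rss / dof)
  if (!is.null(tss)) {
    check_nonneg(tss, "tss")
    out$R2 <- 1 - rss / tss
  }
  if (n > 1) {
    comb <- tibble(profile = "combined", RSS_T = sum(rss),
                   DOF = n * dof, MSE = sum(rss / dof))
    if (!is.null(tss)) comb$R2 <- 1 - sum(rss) / sum(tss)
    out <- dplyr::bind_rows(out, comb)
  }
  out
}
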