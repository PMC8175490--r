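#' Control settings for the grid-search parameter estimation
#'
#' The fit minimizes the total residual sum of squares `RSS_T` by a
#' multiplicative coordinate grid search: in each sweep every free
#' parameter is scanned over `current value x multipliers` and the best
#' improving candidate is accepted. Sweeps are followed by
#' pattern-extrapolation moves (the net log-scale displacement of the
#' last sweep, and of the last `pattern_horizons` sweeps, amplified by
#' `pattern_factors`) which let the search track curved valleys of the
#' objective. When a sweep stalls the multiplier ladder is contracted
#' towards 1 by square roots; the convergence search criterion `csc`
#' (relative `RSS_T` improvement per sweep, study value 1%) stops the
#' search once the ladder is fully contracted.
#'
#' Because the pyruvate affinity constant is weakly identified when
#' substrate levels stay well above it, the fit additionally profiles
#' `profile_param` over an absolute log-spaced grid (clamped inner
#' refits), refines around the winner, and finishes with an all-free
#' polish.
#'
#' @param multipliers Candidate multiplier ladder.
#' @param csc Convergence search criterion: relative `RSS_T`
#'   improvement per sweep below which the search stops (at the finest
#'   ladder contraction). Study value 0.01.
#' @param shrink_tol Relative improvement below which the ladder is
#'   contracted one square-root step.
#' @param max_sweeps Sweep budget of the initial free search.
#' @param profile_param Name of the parameter given the profiled outer
#'   grid (`NULL` disables profiling). Default `"K_ma"`.
#' @param profile_sweeps Sweep budget of each clamped profile refit.
#' @param polish_sweeps Sweep budget of the final all-free polish.
#' @param pattern_factors Amplification factors of pattern moves.
#' @param pattern_horizons Sweep look-back horizons for long-memory
#'   pattern moves.
#' @param bounds Named list of `c(lower, upper)` per parameter;
#'   `NULL` uses start/1000 to start*1000, with the Hill coefficient
#'   restricted to (1, 3] and the lag capped at the sampling interval.
#' @param include_pac Include PAC residuals in the objective (see
#'   [rss_breakdown()]).
#' @param step Integration step of the inner simulations, min.
#' @return An object of class `search_control`.
#' @export
search_control <- function(multipliers = c(0.5, 0.8, 0.9, 0.95,
                                           1.05, 1.1, 1.25, 2),
                           csc = 0.01,
                           shrink_tol = 1e-4,
                           max_sweeps = 400,
                           profile_param = "K_ma",
                           profile_sweeps = 500,
                           polish_sweeps = 1200,
                           pattern_factors = c(1, 2, 4, 8, 16),
                           pattern_horizons = c(5, 20),
                           bounds = NULL,
                           include_pac = TRUE,
                           step = 0.6) {
  if (any(multipliers <= 0)) {
    abort("`multipliers` must be positive", class = "packinetics_config_error")
  }
  if (csc <= 0 || csc >= 1) {
    abort("`csc` must be in (0, 1)", class = "packinetics_config_error")
  }
  structure(list(multipliers = multipliers, csc = csc,
                 shrink_tol = shrink_tol, max_sweeps = max_sweeps,
                 profile_param = profile_param,
                 profile_sweeps = profile_sweeps,
                 polish_sweeps = polish_sweeps,
                 pattern_factors = pattern_factors,
                 pattern_horizons = pattern_horizons,
                 bounds = bounds, include_pac = include_pac,
                 step = step),
            class = "search_control")
}

# default multiplicative box bounds around the starting values
default_bounds <- function(start, profiles) {
  iv <- min(vapply(profiles, function(p) profile_conditions(p)$sampling_interval,
                   numeric(1)))
  b <- lapply(as.list(unclass(start)), function(v) c(v / 1000, v * 1000))
  b$h <- c(max(b$h[1], 1 + 1e-7), min(b$h[2], 3))
  b$t_lag <- c(b$t_lag[1], min(b$t_lag[2], iv))
  b
}

# objective closure over a set of observed profiles: total RSS_T of a
# parameter vector, evaluated by the compiled Euler core
make_objective <- function(profiles, control) {
  obs <- lapply(profiles, profile_matrix)
  conds <- lapply(profiles, profile_conditions)
  y0s <- lapply(conds, function(cn) as.numeric(cn$initial))
  Ph_b <- vapply(conds, function(cn) cn$Ph_b, numeric(1))
  t_end <- vapply(conds, function(cn) cn$t_end, numeric(1))
  interval <- vapply(conds, function(cn) cn$sampling_interval, numeric(1))
  for (i in seq_along(profiles)) {
    expect_t <- seq(0, t_end[i], by = interval[i])
    got_t <- profiles[[i]]$time_min
    if (length(got_t) != length(expect_t) ||
        any(abs(got_t - expect_t) > 1e-9)) {
      abort("fitting profiles must be sampled on the regular grid 0, interval, ..., t_end",
            class = "packinetics_alignment_error")
    }
  }
  force(control)
  function(par) {
    v <- tryCatch(
      .rss_total_core(as.numeric(par), obs, y0s, Ph_b, t_end, interval,
                      control$step, control$include_pac),
      error = function(e) {
        warn(paste0("simulation failed for a candidate; rejected: ",
                    conditionMessage(e)),
             class = "packinetics_candidate_warning")
        Inf
      })
    if (!is.finite(v)) Inf else v
  }
}

# one multiplicative coordinate search with pattern moves.
# `fixed`: parameter names clamped at their current value.
# Returns list(par, value, trace, sweeps, converged).
coordinate_search <- function(par, f, bounds, control,
                              fixed = character(),
                              max_sweeps = control$max_sweeps,
                              csc = control$csc,
                              value = NULL) {
  nm <- names(par)
  free <- setdiff(nm, fixed)
  lower <- vapply(nm, function(n) bounds[[n]][1], numeric(1))
  upper <- vapply(nm, function(n) bounds[[n]][2], numeric(1))
  in_bounds <- function(p) all(p >= lower & p <= upper)
  cur <- value %||% f(par)
  mult <- control$multipliers
  tight_tol <- 2e-4
  trace <- numeric(0)
  hist <- list(par)
  sweeps <- 0L
  converged <- FALSE

  extrapolate <- function(par, cur, ref) {
    ratio <- par / ref
    ratio[fixed] <- 1
    ratio[!is.finite(ratio)] <- 1
    if (all(abs(log(pmax(ratio, 1e-300))) < 1e-12)) {
      return(list(par = par, value = cur))
    }
    for (rep in seq_len(60)) {
      best_v <- cur; best_p <- NULL
      for (fac in control$pattern_factors) {
        cand <- par * ratio^fac
        if (!in_bounds(cand)) next
        v <- f(cand)
        if (v < best_v) { best_v <- v; best_p <- cand }
      }
      if (is.null(best_p)) break
      cur <- best_v; par <- best_p
    }
    list(par = par, value = cur)
  }

  for (sweep in seq_len(max_sweeps)) {
    sweeps <- sweep
    if (cur < 1e-12) { converged <- TRUE; trace <- c(trace, cur); break }
    before <- cur
    par_before <- par
    for (n in free) {
      best_v <- cur; best_x <- NULL
      for (m in mult) {
        cand_x <- par[[n]] * m
        # candidates outside the bounds are never evaluated
        if (cand_x < lower[[n]] || cand_x > upper[[n]]) next
        cand <- par; cand[[n]] <- cand_x
        v <- f(cand)
        if (v < best_v) { best_v <- v; best_x <- cand_x }
      }
      if (!is.null(best_x)) { cur <- best_v; par[[n]] <- best_x }
    }
    res <- extrapolate(par, cur, par_before)
    par <- res$par; cur <- res$value
    for (hz in control$pattern_horizons) {
      if (length(hist) >= hz) {
        res <- extrapolate(par, cur, hist[[length(hist) - hz + 1L]])
        par <- res$par; cur <- res$value
      }
    }
    hist[[length(hist) + 1L]] <- par
    trace <- c(trace, cur)
    rel <- if (before > 0) (before - cur) / before else 0
    tight <- max(abs(mult - 1)) < tight_tol
    if (rel < csc && tight) { converged <- TRUE; break }
    if (rel < control$shrink_tol && !tight) mult <- sqrt(mult)
  }
  list(par = par, value = cur, trace = trace, sweeps = sweeps,
       converged = converged)
}

#' Fit the kinetic parameters to observed profiles by grid search
#'
#' Estimates the ten model constants by minimizing the total residual
#' sum of squares over one or more observed profiles, each simulated
#' under its own reaction conditions. The search strategy (see
#' [search_control()]) is a staged multiplicative grid search: a free
#' coordinate search, a profiled outer grid over the weakly identified
#' pyruvate affinity constant, grid refinement around the winner, and a
#' final all-free polish. All stages accept only improving moves, so
#' the reported `RSS_T` trace is non-increasing.
#'
#' @param profiles A [pac_profile()] or list of them.
#' @param start Starting [kinetic_parameters()] (default: the published
#'   literature starting values).
#' @param control A [search_control()].
#' @return An object of class `pac_fit` with elements `parameters`
#'   (the optimized [kinetic_parameters()]), `value` (final `RSS_T`),
#'   `trace` (tibble of best-so-far `RSS_T` per sweep and stage),
#'   `statistics` (per-profile and combined [fit_statistics()]),
#'   `breakdowns` (per-profile [rss_breakdown()]), `std_errors`
#'   (filled by [parameter_errors()]), plus the inputs.
#' @seealso [validate_fit()], [parameter_errors()], [tidy.pac_fit()]
#' @export
grid_search_fit <- function(profiles, start = pac_parameters_initial(),
                            control = search_control()) {
  if (inherits(profiles, "pac_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "pac_profile")))
  start <- as_kinetic_parameters(start)
  stopifnot(inherits(control, "search_control"))
  bounds <- control$bounds %||% default_bounds(start, profiles)
  par <- as.numeric(start); names(par) <- parameter_names()
  if (!all(vapply(names(par), function(n)
    par[[n]] >= bounds[[n]][1] && par[[n]] <= bounds[[n]][2], logical(1)))) {
    abort("starting values must satisfy the bounds",
          class = "packinetics_config_error")
  }
  f <- make_objective(profiles, control)
  value0 <- f(par)

  trace <- list()
  add_trace <- function(stage, tr) {
    if (length(tr) > 0) {
      trace[[length(trace) + 1L]] <<- tibble(stage = stage,
                                             sweep = seq_along(tr),
                                             RSS_T = tr)
    }
  }

  # stage 1: free coordinate search
  s1 <- coordinate_search(par, f, bounds, control, value = value0)
  add_trace("free_search", s1$trace)
  best <- s1

  # stage 2-3: profiled outer grid over the weakly identified parameter
  pp <- control$profile_param
  if (!is.null(pp) && best$value > 1e-10) {
    km <- best$par[[pp]]
    cand <- unique(sort(c(km * 10^c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2),
                          par[[pp]] * 10^c(-1.5, -1, -0.5, 0))))
    cand <- cand[cand >= bounds[[pp]][1] & cand <= bounds[[pp]][2]]
    for (x in cand) {
      p0 <- best$par; p0[[pp]] <- x
      s <- coordinate_search(p0, f, bounds, control, fixed = pp,
                             max_sweeps = control$profile_sweeps,
                             csc = min(control$csc, 1e-6))
      add_trace(paste0("profile_", pp), pmin(s$trace, best$value))
      if (s$value < best$value) best <- s
    }
    for (fac in 10^(0.25 * 0.5^(0:5))) {
      for (x in c(best$par[[pp]] / fac, best$par[[pp]] * fac)) {
        if (x < bounds[[pp]][1] || x > bounds[[pp]][2]) next
        p0 <- best$par; p0[[pp]] <- x
        s <- coordinate_search(p0, f, bounds, control, fixed = pp,
                               max_sweeps = control$profile_sweeps,
                               csc = min(control$csc, 1e-6))
        add_trace(paste0("refine_", pp), pmin(s$trace, best$value))
        if (s$value < best$value) best <- s
      }
    }
    # stage 4: all-free polish from the winning grid point
    s4 <- coordinate_search(best$par, f, bounds, control,
                            max_sweeps = control$polish_sweeps,
                            csc = min(control$csc, 1e-6),
                            value = best$value)
    add_trace("polish", s4$trace)
    if (s4$value < best$value) best <- s4
  }

  params_hat <- do.call(kinetic_parameters, as.list(best$par))
  breakdowns <- lapply(profiles, function(prof) {
    sim <- simulate_pac(params_hat, profile_conditions(prof),
                        step = control$step)
    rss_breakdown(prof, sim, include_pac = control$include_pac)
  })
  labels <- vapply(seq_along(profiles), function(i)
    profile_label(profiles[[i]]) %||% paste0("profile_", i), character(1))
  n_obs <- vapply(profiles, function(p) nrow(p) * 6L, integer(1))
  stats <- fit_statistics(breakdowns, n_obs = n_obs[1], n_params = 10,
                          tss = vapply(profiles, total_sum_squares,
                                       numeric(1),
                                       include_pac = control$include_pac),
                          labels = labels)

  structure(list(parameters = params_hat,
                 std_errors = NULL,
                 value = best$value,
                 start = start,
                 start_value = value0,
                 trace = dplyr::bind_rows(trace),
                 statistics = stats,
                 breakdowns = setNames(breakdowns, labels),
                 profiles = setNames(profiles, labels),
                 control = control,
                 bounds = bounds,
                 converged = best$converged),
            class = "pac_fit")
}

#' Validate fixed parameters against a held-out profile
#'
#' Simulates the model with fixed (previously estimated) parameters
#' under the conditions of an independent profile and reports the
#' residual breakdown and fit statistics. No parameter is updated; the
#' caller is responsible for the profile not having been used in the
#' fit.
#'
#' @param params A [kinetic_parameters()] object or a `pac_fit`.
#' @param profile A [pac_profile()] not used during fitting.
#' @param step Integration step, min.
#' @param include_pac Include PAC residuals in `RSS_T`.
#' @return A one-row [fit_statistics()] tibble (with `R2`), carrying
#'   the [rss_breakdown()] as attribute `"breakdown"`.
#' @export
validate_fit <- function(params, profile, step = 0.6, include_pac = TRUE) {
  if (inherits(params, "pac_fit")) params <- params$parameters
  params <- as_kinetic_parameters(params)
  stopifnot(inherits(profile, "pac_profile"))
  sim <- simulate_pac(params, profile_conditions(profile), step = step)
  bd <- rss_breakdown(profile, sim, include_pac = include_pac)
  out <- fit_statistics(bd$RSS_T, n_obs = nrow(profile) * 6L,
                        n_params = 10,
                        tss = total_sum_squares(profile,
                                                include_pac = include_pac),
                        labels = profile_label(profile) %||% "validation")
  attr(out, "breakdown") <- bd
  out
}

#' Standard errors of the fitted parameters from observation errors
#'
#' Propagates the observed standard errors through the fit by refitting
#' against the two observation sets shifted to `mean + SE` and
#' `mean - SE`; each parameter's standard error is reported as half the
#' absolute range of its two refitted values. This transparent
#' perturbation scheme stands in for the original study's external
#' error-estimation procedure and is labelled as such in reports.
#'
#' @param fit A `pac_fit` from [grid_search_fit()].
#' @param refit_sweeps Sweep budget of each perturbed refit (an
#'   all-free polish started at the fitted optimum).
#' @return The `pac_fit` with its `std_errors` element filled (named
#'   numeric vector).
#' @export
parameter_errors <- function(fit, refit_sweeps = 150) {
  stopifnot(inherits(fit, "pac_fit"))
  profiles <- fit$profiles
  ses <- lapply(profiles, profile_matrix, what = "se")
  if (all(vapply(ses, function(m) all(m == 0), logical(1)))) {
    inform("all observation standard errors are zero; parameter errors are zero",
           class = "packinetics_log")
    fit$std_errors <- setNames(numeric(10), parameter_names())
    return(fit)
  }
  shift_profiles <- function(sign) {
    lapply(profiles, function(prof) {
      m <- pmax(profile_matrix(prof) + sign * profile_matrix(prof, "se"), 0)
      cols <- species_columns()
      df <- as_tibble(as.data.frame(prof))
      for (s in names(cols)) df[[cols[[s]]]] <- m[, s]
      pac_profile(df, profile_conditions(prof),
                  label = profile_label(prof))
    })
  }
  refit <- function(profs) {
    f <- make_objective(profs, fit$control)
    par <- as.numeric(fit$parameters); names(par) <- parameter_names()
    coordinate_search(par, f, fit$bounds, fit$control,
                      max_sweeps = refit_sweeps,
                      csc = min(fit$control$csc, 1e-3))$par
  }
  p_up <- refit(shift_profiles(+1))
  p_dn <- refit(shift_profiles(-1))
  fit$std_errors <- abs(p_up - p_dn) / 2
  fit
}

#' @export
print.pac_fit <- function(x, ...) {
  cat("<pac_fit> grid-search kinetic parameter estimate\n")
  cat(sprintf("  profiles: %s\n", paste(names(x$profiles), collapse = ", ")))
  cat(sprintf("  RSS_T: %.6g (from %.6g at start, %d sweeps)\n",
              x$value, x$start_value, sum(table(x$trace$stage))))
  print(x$statistics)
  invisible(x)
}

#' Tidy and glance methods for grid-search fits
#'
#' `tidy()` returns one row per kinetic parameter with the estimate and
#' (when [parameter_errors()] has been run) its standard error;
#' `glance()` returns a one-row summary of the combined fit statistics.
#'
#' @param x A `pac_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pac_fit
#' @export
tidy.pac_fit <- function(x, ...) {
  out <- tibble(term = parameter_names(),
                estimate = as.numeric(x$parameters))
  if (!is.null(x$std_errors)) out$std.error <- as.numeric(x$std_errors)
  out
}

#' @rdname tidy.pac_fit
#' @method glance pac_fit
#' @export
glance.pac_fit <- function(x, ...) {
  st <- x$statistics
  comb <- st[st$profile == "combined", ]
  if (nrow(comb) == 0) comb <- st[1, ]
  tibble(RSS_T = comb$RSS_T, MSE = comb$MSE, DOF = comb$DOF,
         R2 = if ("R2" %in% names(comb)) comb$R2 else NA_real_,
         RSS_T_start = x$start_value,
         n_profiles = length(x$profiles),
         converged = x$converged)
}
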