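#' Reaction conditions of a batch biotransformation run
#'
#' @param Ph_b Phosphate (Gomori) buffer concentration in mM. The buffer
#'   concentration drives the zeroth-order enzyme activation term.
#' @param initial Named numeric vector or list with the initial state:
#'   `P` (PAC, mM), `A` (pyruvate, mM), `B` (benzaldehyde, mM),
#'   `Q` (acetaldehyde, mM), `R` (acetoin, mM) and `E` (relative enzyme
#'   activity, %). Missing `Q`/`R` default to 0 (by-products below the
#'   detection limit at start).
#' @param t_end Total reaction time in minutes (study value 210).
#' @param sampling_interval Sampling interval in minutes (study value
#'   30); must divide `t_end`.
#' @param label Optional condition label such as `"100/120"`.
#'
#' @return An object of class `reaction_conditions`.
#' @seealso [pac_study_conditions()] for the published condition sets.
#' @export
reaction_conditions <- function(Ph_b, initial, t_end = 210,
                                sampling_interval = 30, label = NULL) {
  check_scalar(Ph_b, "Ph_b"); check_finite(Ph_b, "Ph_b")
  if (Ph_b <= 0) abort("`Ph_b` must be > 0",
                       class = "packinetics_invalid_argument")
  check_scalar(t_end, "t_end"); check_nonneg(t_end, "t_end")
  if (t_end <= 0) abort("`t_end` must be > 0",
                        class = "packinetics_invalid_argument")
  check_scalar(sampling_interval, "sampling_interval")
  check_nonneg(sampling_interval, "sampling_interval")
  k <- t_end / sampling_interval
  if (abs(k - round(k)) > 1e-9) {
    abort("`sampling_interval` must divide `t_end`",
          class = "packinetics_config_error")
  }
  init <- unlist(initial)
  for (s in c("Q", "R")) if (!s %in% names(init)) init[s] <- 0
  missing <- setdiff(species_codes(), names(init))
  if (length(missing) > 0) {
    abort(paste0("missing initial state component(s): ",
                 paste(missing, collapse = ", ")),
          class = "packinetics_invalid_argument")
  }
  init <- init[species_codes()]
  check_nonneg(init, "initial state")
  structure(
    list(Ph_b = Ph_b, initial = init, t_end = t_end,
         sampling_interval = sampling_interval, label = label),
    class = "reaction_conditions"
  )
}

#' @export
print.reaction_conditions <- function(x, ...) {
  cat("<reaction_conditions>", if (!is.null(x$label)) x$label else "", "\n")
  cat("  phosphate buffer:", x$Ph_b, "mM;  t_end:", x$t_end,
      "min;  sampling every", x$sampling_interval, "min\n")
  cat("  initial state: ",
      paste(sprintf("%s=%g", names(x$initial), x$initial), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Published batch condition sets
#'
#' Apparent initial concentrations of the three benzaldehyde/pyruvate
#' condition pairs of the study, in 250 mM phosphate buffer: measured
#' initial pyruvate, benzaldehyde and PAC concentrations and initial
#' relative enzyme activity for the nominal 30/36, 50/60 and 100/120 mM
#' pairs. By-products start at 0 (not detected).
#'
#' @param pair One of `"30/36"`, `"50/60"`, `"100/120"`.
#' @param Ph_b Phosphate buffer concentration in mM (default 250, the
#'   buffer level of the modelled experiments).
#' @return A [reaction_conditions()] object.
#' @export
#' @examples
#' pac_study_conditions("100/120")
pac_study_conditions <- function(pair = c("100/120", "30/36", "50/60"),
                                 Ph_b = 250) {
  pair <- match.arg(pair)
  init <- switch(pair,
    "30/36"   = c(P = 0.01, A = 35.2, B = 30.9, Q = 0, R = 0, E = 89.4),
    "50/60"   = c(P = 0.01, A = 59.1, B = 50.4, Q = 0, R = 0, E = 96.4),
    "100/120" = c(P = 0.01, A = 116,  B = 100,  Q = 0, R = 0, E = 114)
  )
  reaction_conditions(Ph_b = Ph_b, initial = init, t_end = 210,
                      sampling_interval = 30, label = pair)
}

#' Read or write reaction conditions as JSON/YAML
#'
#' The config keys are `Ph_b_mM`, `t_end_min`, `sampling_interval_min`
#' and a nested `initial` block with `P`, `A`, `B`, `Q`, `R`, `E`.
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return `read_conditions()` returns a [reaction_conditions()] object.
#' @export
read_conditions <- function(path) {
  x <- read_config(path)
  required <- c("Ph_b_mM", "t_end_min", "sampling_interval_min", "initial")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("conditions config missing key(s): ",
                 paste(missing, collapse = ", ")),
          class = "packinetics_io_error")
  }
  reaction_conditions(Ph_b = x$Ph_b_mM, initial = x$initial,
                      t_end = x$t_end_min,
                      sampling_interval = x$sampling_interval_min,
                      label = x$label %||% NULL)
}

#' @rdname read_conditions
#' @param conditions A [reaction_conditions()] object.
#' @export
write_conditions <- function(conditions, path) {
  stopifnot(inherits(conditions, "reaction_conditions"))
  x <- list(Ph_b_mM = conditions$Ph_b,
            t_end_min = conditions$t_end,
            sampling_interval_min = conditions$sampling_interval,
            initial = as.list(conditions$initial))
  if (!is.null(conditions$label)) x$label <- conditions$label
  write_config(x, path)
  invisible(path)
}
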