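#' Construct an experimental profile
#'
#' An experimental profile holds replicate-averaged observations of the
#' six measured quantities (pyruvate, benzaldehyde, PAC, acetaldehyde,
#' acetoin in mM; relative enzyme activity in %) at the sampling times
#' of one batch run, together with their standard errors and the
#' reaction conditions.
#'
#' @param data A data frame with column `time_min` and the six
#'   measurement columns `pyruvate_mM`, `benzaldehyde_mM`, `pac_mM`,
#'   `acetaldehyde_mM`, `acetoin_mM`, `enzyme_pct`; optional matching
#'   `*_se` columns (missing ones default to 0).
#' @param conditions A [reaction_conditions()] object.
#' @param label Condition label (defaults to the conditions' label).
#' @param replicates Number of replicates behind the means (metadata).
#' @return A tibble of class `pac_profile`.
#' @export
pac_profile <- function(data, conditions, label = NULL, replicates = NA_integer_) {
  stopifnot(inherits(conditions, "reaction_conditions"))
  data <- as_tibble(data)
  required <- profile_column_order(se = FALSE)
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("profile is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "packinetics_parse_error")
  }
  se_cols <- paste0(setdiff(required, "time_min"), "_se")
  for (sc in se_cols) if (!sc %in% names(data)) data[[sc]] <- 0
  data <- data[, profile_column_order(se = TRUE)]
  if (nrow(data) < 1) {
    abort("profile has no observations", class = "packinetics_parse_error")
  }
  t <- data$time_min
  if (t[1] != 0 || any(diff(t) <= 0)) {
    abort("`time_min` must be strictly increasing and start at 0",
          class = "packinetics_parse_error")
  }
  for (cl in setdiff(names(data), "time_min")) {
    if (any(!is.finite(data[[cl]])) || any(data[[cl]] < 0)) {
      abort(paste0("column `", cl, "` must be finite and non-negative"),
            class = "packinetics_parse_error")
    }
  }
  structure(data,
            class = c("pac_profile", class(data)),
            conditions = conditions,
            label = label %||% conditions$label,
            replicates = replicates)
}

#' Reaction conditions and label of a profile
#'
#' @param profile A `pac_profile`.
#' @return The [reaction_conditions()] object (or label string) stored
#'   with the profile.
#' @export
profile_conditions <- function(profile) {
  stopifnot(inherits(profile, "pac_profile"))
  attr(profile, "conditions")
}

#' @rdname profile_conditions
#' @export
profile_label <- function(profile) {
  stopifnot(inherits(profile, "pac_profile"))
  attr(profile, "label")
}

# observations as an n x 6 matrix in canonical species order P,A,B,Q,R,E
profile_matrix <- function(profile, what = c("mean", "se")) {
  what <- match.arg(what)
  cols <- species_columns()
  if (what == "se") cols <- paste0(cols, "_se")
  m <- as.matrix(as.data.frame(profile)[, cols])
  dimnames(m) <- list(NULL, species_codes())
  m
}
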