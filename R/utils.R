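# internal input checks ------------------------------------------------------

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric, got %s", what,
                  paste(utils::head(x, 3), collapse = ", ")),
          class = "packinetics_invalid_argument")
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  check_finite(x, what)
  if (any(x < 0)) {
    abort(sprintf("`%s` must be non-negative", what),
          class = "packinetics_invalid_argument")
  }
  invisible(x)
}

check_scalar <- function(x, what) {
  if (length(x) != 1L) {
    abort(sprintf("`%s` must be a single value", what),
          class = "packinetics_invalid_argument")
  }
  invisible(x)
}

# species bookkeeping ---------------------------------------------------------

# canonical state order used throughout: P, A, B, Q, R, E
species_codes <- function() c("P", "A", "B", "Q", "R", "E")

# column names of the tabular profile/trajectory format
species_columns <- function() {
  c(P = "pac_mM", A = "pyruvate_mM", B = "benzaldehyde_mM",
    Q = "acetaldehyde_mM", R = "acetoin_mM", E = "enzyme_pct")
}

profile_column_order <- function(se = FALSE) {
  base <- c("time_min", "pyruvate_mM", "benzaldehyde_mM", "pac_mM",
            "acetaldehyde_mM", "acetoin_mM", "enzyme_pct")
  if (!se) return(base)
  meas <- setdiff(base, "time_min")
  c(base, paste0(meas, "_se"))
}
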