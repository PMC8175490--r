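#' Read and write experimental profiles as CSV
#'
#' Profiles are stored as RFC-4180-style comma-separated text with
#' UTF-8 encoding, optional `#`-prefixed metadata lines before the
#' header (`# label: ...`, `# Ph_b_mM: ...`, `# replicates: ...`), the
#' column order `time_min, pyruvate_mM, benzaldehyde_mM, pac_mM,
#' acetaldehyde_mM, acetoin_mM, enzyme_pct` plus matching `*_se`
#' columns, and 6-significant-digit numeric formatting. Missing `*_se`
#' columns read as 0.
#'
#' @param path File path.
#' @param conditions Optional [reaction_conditions()]; when `NULL`,
#'   conditions are reconstructed from the metadata lines and the data
#'   (initial row, time grid).
#' @return `read_profile()` returns a [pac_profile()];
#'   `write_profile()` returns `path` invisibly.
#' @export
read_profile <- function(path, conditions = NULL) {
  if (!file.exists(path)) {
    abort(paste0("profile file not found: ", path),
          class = "packinetics_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    sep <- regexpr(":", kv, fixed = TRUE)
    if (sep > 0) {
      meta[[trimws(substr(kv, 1, sep - 1))]] <-
        trimws(substr(kv, sep + 1, nchar(kv)))
    }
  }
  df <- readr::read_csv(I(lines[!grepl("^#", lines)]),
                        show_col_types = FALSE, progress = FALSE)
  required <- profile_column_order(se = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("profile file ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "packinetics_parse_error")
  }
  for (cl in names(df)) {
    bad <- which(!is.finite(df[[cl]]) | df[[cl]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("invalid value in column `%s`, row %d of %s",
                    cl, bad[1], path),
            class = "packinetics_parse_error")
    }
  }
  if (any(diff(df$time_min) <= 0)) {
    abort(paste0("`time_min` must be strictly increasing in ", path),
          class = "packinetics_parse_error")
  }
  if (is.null(conditions)) {
    iv <- if (nrow(df) > 1) df$time_min[2] - df$time_min[1] else 30
    conditions <- reaction_conditions(
      Ph_b = as.numeric(meta[["Ph_b_mM"]] %||% 250),
      initial = c(P = df$pac_mM[1], A = df$pyruvate_mM[1],
                  B = df$benzaldehyde_mM[1], Q = df$acetaldehyde_mM[1],
                  R = df$acetoin_mM[1], E = df$enzyme_pct[1]),
      t_end = max(df$time_min), sampling_interval = iv,
      label = meta[["label"]] %||% NULL)
  }
  reps <- suppressWarnings(as.integer(meta[["replicates"]] %||% NA))
  pac_profile(df, conditions, label = meta[["label"]] %||% NULL,
              replicates = reps)
}

#' @rdname read_profile
#' @param profile A [pac_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "pac_profile"))
  if (nrow(profile) == 0) {
    abort("refusing to write an empty profile",
          class = "packinetics_io_error")
  }
  cond <- profile_conditions(profile)
  cols <- profile_column_order(se = TRUE)
  df <- as.data.frame(profile)[, cols]
  df[] <- lapply(df, function(x) signif(x, 6))
  con <- file(path, open = "wb")  # binary mode: deterministic newlines
  on.exit(close(con))
  label <- profile_label(profile)
  if (!is.null(label)) writeLines(paste0("# label: ", label), con)
  writeLines(paste0("# Ph_b_mM: ", format(cond$Ph_b, scientific = FALSE)), con)
  reps <- attr(profile, "replicates")
  if (!is.na(reps %||% NA)) writeLines(paste0("# replicates: ", reps), con)
  writeLines(paste(cols, collapse = ","), con)
  writeLines(apply(df, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = ",")), con)
  invisible(path)
}

#' Run the complete estimation-and-validation study
#'
#' Orchestrates the published workflow on a set of profiles: fit the
#' kinetic parameters by grid search on the fitting profiles, validate
#' them against held-out profile(s), optionally estimate parameter
#' standard errors, and write a JSON fit report plus simulated
#' trajectory CSVs.
#'
#' @param config A named list (or path to a JSON/YAML file) with
#'   elements:
#'   \describe{
#'     \item{`fit_profiles`}{list of [pac_profile()] objects or CSV
#'       paths used for estimation.}
#'     \item{`validation_profiles`}{profiles or CSV paths held out for
#'       validation (optional).}
#'     \item{`start`}{starting parameters: a [kinetic_parameters()],
#'       a named list, or a JSON/YAML path (default: literature
#'       starting values).}
#'     \item{`control`}{a [search_control()] or named list of its
#'       arguments (optional).}
#'     \item{`parameter_errors`}{logical, run [parameter_errors()]
#'       (default `FALSE`).}
#'     \item{`out_dir`}{output directory for `fit_report.json` and
#'       trajectory CSVs (optional; no files written when `NULL`).}
#'   }
#' @return A list of class `pac_study` with elements `fit` (the
#'   [grid_search_fit()] result), `validation` (tibble of validation
#'   statistics), and `report` (the report list written to JSON).
#' @export
run_study <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  stopifnot(is.list(config))
  load_profiles <- function(x) {
    if (is.null(x)) return(list())
    if (inherits(x, "pac_profile")) return(list(x))
    lapply(x, function(p) if (inherits(p, "pac_profile")) p
           else read_profile(p))
  }
  fit_profiles <- load_profiles(config$fit_profiles)
  if (length(fit_profiles) == 0) {
    abort("`config$fit_profiles` must name at least one profile",
          class = "packinetics_config_error")
  }
  val_profiles <- load_profiles(config$validation_profiles)

  fit_labels <- vapply(fit_profiles, function(p)
    profile_label(p) %||% "", character(1))
  val_labels <- vapply(val_profiles, function(p)
    profile_label(p) %||% "", character(1))
  overlap <- intersect(fit_labels[nzchar(fit_labels)],
                       val_labels[nzchar(val_labels)])
  if (length(overlap) > 0) {
    warn(paste0("validation profile(s) also listed for fitting: ",
                paste(overlap, collapse = ", ")),
         class = "packinetics_holdout_warning")
  }

  start <- config$start %||% pac_parameters_initial()
  if (is.character(start)) start <- read_parameters(start)
  start <- as_kinetic_parameters(start)
  control <- config$control %||% search_control()
  if (!inherits(control, "search_control")) {
    control <- do.call(search_control, control)
  }

  inform(sprintf(
    "run_study: step = %g min, include_pac = %s, CSC = %g, DOF convention = n_obs - 10",
    control$step, control$include_pac, control$csc),
    class = "packinetics_log")

  fit <- grid_search_fit(fit_profiles, start = start, control = control)
  if (isTRUE(config$parameter_errors)) fit <- parameter_errors(fit)

  validation <- NULL
  if (length(val_profiles) > 0) {
    validation <- dplyr::bind_rows(lapply(val_profiles, function(p)
      validate_fit(fit$parameters, p, step = control$step,
                   include_pac = control$include_pac)))
  }

  report <- list(
    parameters = as.list(unclass(fit$parameters)),
    parameter_std_errors = if (!is.null(fit$std_errors))
      as.list(fit$std_errors) else NULL,
    std_error_method = if (!is.null(fit$std_errors))
      "half-range of refits against mean +/- SE observations" else NULL,
    fit_statistics = as.data.frame(fit$statistics),
    rss_breakdown = lapply(fit$breakdowns, as.list),
    validation_statistics = if (!is.null(validation))
      as.data.frame(validation) else NULL,
    search = list(RSS_T_start = fit$start_value,
                  RSS_T_final = fit$value,
                  converged = fit$converged,
                  csc = control$csc,
                  step_min = control$step,
                  include_pac = control$include_pac,
                  multipliers = control$multipliers),
    trace = as.data.frame(fit$trace)
  )

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    for (p in c(fit_profiles, val_profiles)) {
      cond <- profile_conditions(p)
      traj <- simulate_pac(fit$parameters, cond, step = control$step)
      lab <- gsub("[^A-Za-z0-9]+", "_", profile_label(p) %||% "profile")
      write_trajectory(traj, file.path(out_dir,
                                       paste0("trajectory_", lab, ".csv")))
    }
  }

  structure(list(fit = fit, validation = validation, report = report),
            class = "pac_study")
}

#' @export
print.pac_study <- function(x, ...) {
  cat("<pac_study>\n")
  print(x$fit)
  if (!is.null(x$validation)) {
    cat("validation:\n")
    print(x$validation)
  }
  invisible(x)
}
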