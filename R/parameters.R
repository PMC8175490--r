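#' Kinetic parameters of the PAC biotransformation model
#'
#' Bundles the ten rate constants of the six-state model of batch
#' (R)-phenylacetylcarbinol (PAC) formation by pyruvate decarboxylase
#' (PDC): PAC formation follows a Hill-type benzaldehyde binding term
#' multiplied by a Michaelis-Menten pyruvate saturation term and by the
#' relative enzyme activity; acetaldehyde and acetoin arise from direct
#' pyruvate decarboxylation; and the enzyme deactivates at a first-order
#' rate (background plus benzaldehyde-dependent) partly offset by a
#' zeroth-order activation by phosphate buffer species, after an initial
#' lag of constant activity.
#'
#' @param V_p Overall PAC formation rate constant (mM min^-1 %^-1).
#' @param K_b Intrinsic benzaldehyde binding constant (mM^(1-h)).
#' @param h Hill coefficient for benzaldehyde binding (dimensionless).
#'   Values near 2 indicate a cooperatively acting dimeric enzyme form.
#' @param K_ma Pyruvate affinity constant (mM).
#' @param V_q Acetaldehyde formation rate constant (min^-1 %^-1).
#' @param V_r Acetoin formation rate constant (min^-1 mM^-1 %^-1).
#' @param k_d1 First-order background deactivation constant (min^-1).
#' @param k_d2 First-order benzaldehyde-dependent deactivation constant
#'   (min^-1 mM^-1).
#' @param k_a Zeroth-order activation rate constant due to phosphate
#'   buffer species (% min^-1 mM^-1).
#' @param t_lag Initial period of constant enzyme activity (min).
#'
#' @details All constants must be finite and non-negative; `t_lag` may be
#'   zero. Strict positivity and the physically sensible Hill range
#'   `1 < h <= 3` are enforced as fitting bounds (see
#'   [search_control()]), not as construction errors, so that degenerate
#'   parameter sets (e.g. a switched-off pathway) remain representable.
#'
#' @return An object of class `kinetic_parameters`: a named numeric
#'   vector of length ten.
#' @seealso [pac_parameters_initial()], [pac_parameters_optimized()]
#' @export
#' @examples
#' kinetic_parameters(V_p = 6.71e-2, K_b = 1.01e-4, h = 1.94, K_ma = 0.70,
#'                    V_q = 1.68e-5, V_r = 6.06e-6, k_d1 = 5.99e-3,
#'                    k_d2 = 1.33e-5, k_a = 9.38e-6, t_lag = 0.42)
kinetic_parameters <- function(V_p, K_b, h, K_ma, V_q, V_r,
                               k_d1, k_d2, k_a, t_lag) {
  p <- c(V_p = V_p, K_b = K_b, h = h, K_ma = K_ma, V_q = V_q, V_r = V_r,
         k_d1 = k_d1, k_d2 = k_d2, k_a = k_a, t_lag = t_lag)
  check_finite(p, "kinetic parameters")
  check_nonneg(p, "kinetic parameters")
  structure(p, class = "kinetic_parameters")
}

parameter_names <- function() {
  c("V_p", "K_b", "h", "K_ma", "V_q", "V_r", "k_d1", "k_d2", "k_a", "t_lag")
}

as_kinetic_parameters <- function(x) {
  if (inherits(x, "kinetic_parameters")) return(x)
  x <- unlist(x)
  missing <- setdiff(parameter_names(), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing kinetic parameter(s): ",
                 paste(missing, collapse = ", ")),
          class = "packinetics_invalid_argument")
  }
  do.call(kinetic_parameters, as.list(x[parameter_names()]))
}

#' Literature starting values for the kinetic parameters
#'
#' The published starting point of the parameter search: rate constants
#' averaged from earlier initial-rate and batch biotransformation studies
#' of partially purified *Candida utilis* PDC in MOPS buffer, and
#' deactivation/activation constants from a whole-cell *C. tropicalis*
#' PDC stability study in phosphate buffer.
#'
#' @return A [kinetic_parameters()] object.
#' @export
pac_parameters_initial <- function() {
  kinetic_parameters(V_p = 1.55e-2, K_b = 9.00e-5, h = 1.98, K_ma = 4.84,
                     V_q = 6.38e-6, V_r = 9.88e-7, k_d1 = 8.89e-3,
                     k_d2 = 3.30e-5, k_a = 1.34e-5, t_lag = 1.00)
}

#' Optimized kinetic parameters for partially purified C. tropicalis PDC
#'
#' The published optimum of the grid search against the 30/36 and
#' 100/120 mM benzaldehyde/pyruvate batch profiles in 250 mM phosphate
#' buffer. Useful as ground truth for synthetic-data experiments and as
#' a realistic simulation default.
#'
#' @return A [kinetic_parameters()] object.
#' @export
pac_parameters_optimized <- function() {
  kinetic_parameters(V_p = 6.71e-2, K_b = 1.01e-4, h = 1.94, K_ma = 0.70,
                     V_q = 1.68e-5, V_r = 6.06e-6, k_d1 = 5.99e-3,
                     k_d2 = 1.33e-5, k_a = 9.38e-6, t_lag = 0.42)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("<kinetic_parameters>\n")
  print(format(unclass(x), digits = 4, scientific = TRUE), quote = FALSE)
  invisible(x)
}

#' Tidy a set of kinetic parameters
#'
#' @param x A `kinetic_parameters` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy kinetic_parameters
#' @export
tidy.kinetic_parameters <- function(x, ...) {
  tibble(term = names(unclass(x)), estimate = as.numeric(x))
}

#' Read or write kinetic parameters as JSON/YAML
#'
#' Configuration files use the flat keys `V_p, K_b, h, K_ma, V_q, V_r,
#' k_d1, k_d2, k_a, t_lag`. The format is inferred from the file
#' extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return `read_parameters()` returns a [kinetic_parameters()] object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  x <- read_config(path)
  as_kinetic_parameters(x)
}

#' @rdname read_parameters
#' @param params A [kinetic_parameters()] object (or coercible list).
#' @export
write_parameters <- function(params, path) {
  params <- as_kinetic_parameters(params)
  write_config(as.list(unclass(params)), path)
  invisible(path)
}

read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "packinetics_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    abort(paste0("unsupported config format: .", ext, " (use JSON or YAML)"),
          class = "packinetics_io_error")
  }
}

write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    abort(paste0("unsupported config format: .", ext, " (use JSON or YAML)"),
          class = "packinetics_io_error")
  }
  invisible(path)
}
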