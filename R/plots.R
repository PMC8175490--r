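profile_long <- function(df, se = FALSE) {
  cols <- unname(species_columns())
  keep <- c("time_min", intersect(cols, names(df)))
  long <- tidyr::pivot_longer(as_tibble(df)[, keep], -"time_min",
                              names_to = "species", values_to = "value")
  if (se) {
    se_cols <- paste0(cols, "_se")
    if (all(se_cols %in% names(df))) {
      se_long <- tidyr::pivot_longer(as_tibble(df)[, c("time_min", se_cols)],
                                     -"time_min",
                                     names_to = "species", values_to = "se")
      se_long$species <- sub("_se$", "", se_long$species)
      long <- dplyr::left_join(long, se_long, by = c("time_min", "species"))
    }
  }
  long$species <- factor(long$species, levels = cols)
  long
}

#' Plot a simulated trajectory
#'
#' Concentration and enzyme-activity time courses of a simulated batch
#' run, one panel per quantity.
#'
#' @param object A `pac_trajectory` from [simulate_pac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pac_trajectory
#' @export
autoplot.pac_trajectory <- function(object, ...) {
  long <- profile_long(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c6e91") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (mM) / activity (%)",
                  title = "Simulated PAC biotransformation") +
    ggplot2::theme_minimal()
}

#' Plot an observed profile
#'
#' Observed replicate means with standard-error bars, one panel per
#' measured quantity.
#'
#' @param object A [pac_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pac_profile
#' @export
autoplot.pac_profile <- function(object, ...) {
  long <- profile_long(object, se = TRUE)
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min,
                                           y = .data$value)) +
    ggplot2::geom_point(colour = "#7a3b74")
  if ("se" %in% names(long)) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$se,
                   ymax = .data$value + .data$se),
      width = 4, colour = "#7a3b74")
  }
  gg +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (mM) / activity (%)",
                  title = paste("Observed profile",
                                profile_label(object) %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a fit: observed points against fitted curves
#'
#' Overlays the fitted model simulation (lines) on the observed
#' replicate means (points) for every profile of a grid-search fit.
#'
#' @param object A `pac_fit` from [grid_search_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pac_fit
#' @export
autoplot.pac_fit <- function(object, ...) {
  obs <- dplyr::bind_rows(lapply(names(object$profiles), function(lab) {
    long <- profile_long(object$profiles[[lab]])
    long$profile <- lab
    long
  }))
  sim <- dplyr::bind_rows(lapply(names(object$profiles), function(lab) {
    cond <- profile_conditions(object$profiles[[lab]])
    traj <- simulate_pac(object$parameters, cond,
                         step = object$control$step)
    long <- profile_long(traj)
    long$profile <- lab
    long
  }))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(data = sim, colour = "#2c6e91") +
    ggplot2::geom_point(size = 1, colour = "#7a3b74") +
    ggplot2::facet_grid(species ~ profile, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (mM) / activity (%)",
                  title = "Grid-search fit: observed (points) vs model (lines)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
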