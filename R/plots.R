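# Diagnostic figures. Each result type gets a ggplot2 helper; the functions
# return the plot object so callers can theme or facet further.

#' Plot per-species cover trajectories
#'
#' @param trajectory Tibble `step, species, cover_cm2` from [run_ipm()] or
#'   [simulate_ibm()].
#' @return A ggplot object.
#' @export
plot_cover_trajectory <- function(trajectory) {
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = .data$step, y = .data$cover_cm2,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = expression(cover ~ (cm^2)),
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot negative frequency dependence
#'
#' One line per species through (frequency ~ 0, invasion growth rate) and
#' (equilibrium frequency, 0); the slope is the NFD measure.
#'
#' @param object An `nfd_result` from [nfd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nfd_result <- function(object, ...) {
  segs <- object |>
    mutate(x0 = 0, y0 = .data$igr, x1 = .data$frequency, y1 = 0)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       colour = .data$species)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "frequency (relative cover)",
                  y = "per-capita growth rate (log)", colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot a perturbation-effect decomposition
#'
#' Proportional full, direct and indirect effects per species and
#' perturbation kind.
#'
#' @param object A `perturbation_result` from [perturbation_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perturbation_result <- function(object, ...) {
  long <- object |>
    select("species", "perturbation", "prop_full", "prop_direct",
           "prop_indirect") |>
    pivot_longer(c("prop_full", "prop_direct", "prop_indirect"),
                 names_to = "effect", values_to = "value") |>
    mutate(effect = sub("^prop_", "", .data$effect))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$value,
                                     fill = .data$effect)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~perturbation) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(y = "proportional change in equilibrium cover",
                  fill = "effect") +
    ggplot2::theme_minimal()
}

#' Plot hindcast predicted versus observed cover
#'
#' @param pred Output of [simulate_historical()].
#' @return A ggplot object.
#' @export
plot_historical_fit <- function(pred) {
  long <- pred |>
    pivot_longer(c("cover_pred", "cover_obs"), names_to = "series",
                 values_to = "cover") |>
    mutate(series = ifelse(.data$series == "cover_pred", "predicted", "observed"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$cover,
                                     colour = .data$species,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quadrat) +
    ggplot2::labs(y = expression(cover ~ (cm^2))) +
    ggplot2::theme_minimal()
}

#' @export
tidy.climate_selection <- function(x, ...) x$trace

#' @export
glance.climate_selection <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 final_AIC = tail(x$trace$AIC, 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
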