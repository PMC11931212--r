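# ggplot2 displays for the main result types.

#' Plot total attributable cost by entering cohort
#'
#' Bar chart of lifetime discounted attributable cost per 5-year cohort,
#' faceted by sex.
#'
#' @param x An `st_country_burden` from [aggregate_country()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_country_burden <- function(x, ...) {
  x |>
    dplyr::mutate(entry_band = factor(.data$entry_band,
                                      levels = unique(.data$entry_band))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$entry_band,
                                 y = .data$total_cost_saved / 1e3)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(
      x = "Age cohort at model start",
      y = "Lifetime attributable cost (US$, thousands)",
      title = paste0("Lifetime discounted costs attributable to smokeless tobacco",
                     if (!is.null(attr(x, "country"))) paste0(" (", attr(x, "country"), ")"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot cost attribution by state at entry
#'
#' Stacked proportions of the attributable cost borne by those entering the
#' model as never, current and former users, across cohorts.
#'
#' @param bundle An [st_bundle()].
#' @param schedule An [st_schedule()].
#' @param sexes Sexes to include.
#' @return A ggplot object.
#' @export
plot_attribution <- function(bundle, schedule = bundle$schedule,
                             sexes = bundle$config$sexes) {
  dat <- purrr::map_dfr(sexes, function(sx) {
    purrr::map_dfr(bundle$config$entry_bands, function(b) {
      attribute_by_entry_state(bundle, sx, b, schedule) |>
        dplyr::mutate(sex = sx, entry_band = b)
    })
  }) |>
    dplyr::mutate(
      entry_band = factor(.data$entry_band,
                          levels = bundle$config$entry_bands),
      entry_state = factor(.data$entry_state,
                           levels = c("never", "current", "former"))
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$entry_band, y = .data$share,
                                    fill = .data$entry_state)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(x = "Age cohort at model start",
                  y = "Share of attributable cost",
                  fill = "State at entry",
                  title = "Attributable cost by smokeless tobacco use state at entry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot PSA credible intervals
#'
#' Point estimates with 95% credible intervals per cohort for one output.
#'
#' @param x An `st_psa`.
#' @param output Which output to display (default `"cost_saved"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_psa <- function(x, output = "cost_saved", ...) {
  x$summary |>
    dplyr::filter(.data$output == !!output) |>
    dplyr::mutate(entry_band = factor(.data$entry_band,
                                      levels = unique(.data$entry_band))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$entry_band, y = .data$point)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(x = "Age cohort at model start", y = output,
                  title = sprintf("%s with 95%% credible intervals (%d draws)",
                                  output, x$n_draws)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a cohort trace
#'
#' Stacked state occupancy over age for one cohort run.
#'
#' @param x An `st_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_trace <- function(x, ...) {
  dat <- tibble::as_tibble(x) |>
    dplyr::mutate(former = rowSums(dplyr::across(dplyr::starts_with("former")))) |>
    dplyr::select("age", "never", "current", "former", "dead") |>
    tidyr::pivot_longer(-"age", names_to = "state", values_to = "occupancy") |>
    dplyr::mutate(state = factor(.data$state,
                                 levels = c("never", "current", "former", "dead")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                    fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age", y = "Occupancy",
                  title = paste0(attr(x, "sex"), " cohort entering at ",
                                 attr(x, "entry_band"), " (",
                                 attr(x, "scenario"), ")")) +
    ggplot2::theme_minimal()
}
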