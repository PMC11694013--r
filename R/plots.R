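#' Plot an abridged life table
#'
#' Survivorship (`l`, per 100 000) and remaining life expectancy (`e`)
#' against age.
#'
#' @param object An `abridged_life_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot abridged_life_table
#' @export
autoplot.abridged_life_table <- function(object, ...) {
  df <- tidy(object) |>
    select("age_start", survivors = "l", life_expectancy = "e") |>
    tidyr::pivot_longer(-"age_start", names_to = "column")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_start, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~column, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot life-expectancy trends across the ten Americas
#'
#' Point estimates by year with uncertainty ribbons, one line per
#' America.
#'
#' @param grid A summarised grid (e.g. `life_expectancy` from
#'   [run_pipeline()] filtered to one quantity, or
#'   [load_published_life_expectancy()]).
#' @param quantity Quantity to plot when a `quantity` column is present
#'   (default `"e0"`).
#' @return A ggplot object.
#' @export
plot_life_expectancy <- function(grid, quantity = "e0") {
  if ("quantity" %in% names(grid)) {
    grid <- grid |> filter(.data$quantity == !!quantity)
  }
  if ("sex" %in% names(grid) && length(unique(grid$sex)) > 1) {
    grid <- grid |> filter(.data$sex == "both")
  }
  p <- ggplot2::ggplot(grid,
                       ggplot2::aes(x = .data$year, y = .data$mean,
                                    colour = factor(.data$america_id),
                                    group = .data$america_id))
  if (all(c("lower", "upper") %in% names(grid))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                   fill = factor(.data$america_id)),
      alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "year", y = "life expectancy at birth (years)",
                  colour = "America", fill = "America") +
    ggplot2::theme_minimal()
}

#' @method autoplot disparity_report
#' @export
autoplot.disparity_report <- function(object, ...) {
  ggplot2::ggplot(object$gaps,
                  ggplot2::aes(x = .data$year, y = .data$gap)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "year",
                  y = "highest-to-lowest life expectancy gap (years)") +
    ggplot2::theme_minimal()
}

#' @method tidy disparity_report
#' @export
tidy.disparity_report <- function(x, ...) x$gaps

#' @method glance disparity_report
#' @export
glance.disparity_report <- function(x, ...) {
  tibble(n_years = nrow(x$gaps),
         max_gap = max(x$gaps$gap),
         year_max_gap = x$gaps$year[which.max(x$gaps$gap)])
}

#' @method tidy recovery_study
#' @export
tidy.recovery_study <- function(x, ...) x$results

#' @method glance recovery_study
#' @export
glance.recovery_study <- function(x, ...) {
  tibble(n_replicates = x$n_replicates, n_sims = x$n_sims,
         overall_coverage = x$overall_coverage,
         mae_corrected = mean(x$summary$mae_corrected),
         mae_uncorrected = mean(x$summary$mae_uncorrected))
}

#' @method tidy ten_americas_run
#' @export
tidy.ten_americas_run <- function(x, ...) x$life_expectancy

#' @method glance ten_americas_run
#' @export
glance.ten_americas_run <- function(x, ...) {
  e0 <- x$life_expectancy |>
    filter(.data$quantity == "e0", .data$sex == "both")
  yr <- max(e0$year)
  gap <- compute_gap(e0 |> filter(.data$year == yr), yr)
  tibble(n_sims = x$manifest$n_sims, n_counties = x$manifest$n_counties,
         final_year = yr, gap_final_year = gap$gap)
}
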