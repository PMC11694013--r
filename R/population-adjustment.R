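#' Split the "Two or More Races" population onto single races
#'
#' Population reported in a `multirace` category is allocated to the
#' single races in proportion to the cell's single-race composition and
#' added to the single-race totals; per-cell total population is
#' conserved exactly.
#'
#' @param population Population tibble (`value`), possibly with
#'   `multirace` rows.
#' @param composition Optional [race_composition()] table; computed from
#'   `population` itself when `NULL`.
#' @param by Cell key columns.
#' @return The population series without `multirace` rows.
#' @export
split_two_or_more_races <- function(population, composition = NULL,
                                    by = c("year", "county_id",
                                           "age_group", "sex")) {
  if (is.null(composition)) composition <- race_composition(population, by)
  bridge_multirace_deaths(population, composition, by)
}

#' Estimate the census-base discrepancy per cell
#'
#' Fits a log-linear trend to each cell's population over the years
#' immediately before the new census base and extrapolates it to the
#' base year; the discrepancy is the observed base-year value minus the
#' extrapolated one — the error of closure that intercensal estimates
#' distribute back over the decade.
#'
#' @param series Population tibble without `multirace` rows.
#' @param base_year First year on the new census base.
#' @param fit_years How many pre-base years to fit the trend on.
#' @return Tibble of cell keys with a `discrepancy` column (persons).
#' @export
estimate_base_discrepancy <- function(series, base_year, fit_years = 4) {
  pre <- series |>
    filter(.data$year < base_year, .data$year >= base_year - fit_years)
  if (nrow(pre) == 0) abort("base_year leaves no pre-base years to fit")
  key <- c("county_id", "age_group", "sex", "race")
  trend <- pre |>
    group_by(across(all_of(key))) |>
    summarise(
      growth = if (dplyr::n() > 1) {
        unname(exp(stats::coef(stats::lm(log(pmax(value, 1e-9)) ~ year))[2]))
      } else 1,
      last_value = .data$value[which.max(.data$year)],
      last_year = max(.data$year),
      .groups = "drop"
    )
  base <- series |>
    filter(.data$year == base_year) |>
    select(all_of(key), base_value = "value")
  trend |>
    inner_join(base, by = key) |>
    mutate(expected = .data$last_value *
             .data$growth^(base_year - .data$last_year),
           discrepancy = .data$base_value - .data$expected) |>
    select(all_of(key), "discrepancy")
}

#' Blend away a census-base discontinuity
#'
#' Adjusts the pre-base segment of a population series so it meets the
#' new census base smoothly, in the spirit of intercensal estimation:
#' the base-year discrepancy is phased in with a weight rising linearly
#' from 0 at the window start to 1 at the base year.
#' `linear_additive` (default) adds `w(t) x discrepancy`;
#' `linear_multiplicative` applies the equivalent ratio
#' `(base / (base - discrepancy))^{w(t)}`.  Cells that an additive blend
#' would drive negative are floored at 0 and counted in a message.
#'
#' @param series Population tibble without `multirace` rows.
#' @param base_discrepancy Output of [estimate_base_discrepancy()].
#' @param base_year First year on the new census base; must lie inside
#'   the series' year range.
#' @param window_start Year at which the blend weight is 0; defaults to
#'   the earliest year in the series.
#' @param method `"linear_additive"` or `"linear_multiplicative"`.
#' @return The adjusted series (years at or after `base_year` are
#'   unchanged).
#' @export
intercensal_blend <- function(series, base_discrepancy, base_year,
                              window_start = NULL,
                              method = c("linear_additive",
                                         "linear_multiplicative")) {
  method <- match.arg(method)
  yrs <- range(series$year)
  if (base_year < yrs[1] || base_year > yrs[2]) {
    abort("base_year lies outside the series' year range")
  }
  window_start <- window_start %||% yrs[1]
  key <- c("county_id", "age_group", "sex", "race")
  out <- series |>
    left_join(base_discrepancy, by = key) |>
    mutate(discrepancy = dplyr::coalesce(.data$discrepancy, 0),
           w = pmax(0, pmin(1, (.data$year - window_start) /
                              (base_year - window_start))),
           w = ifelse(.data$year >= base_year, NA_real_, .data$w))
  pre <- !is.na(out$w)
  if (method == "linear_additive") {
    adj <- out$value[pre] + out$w[pre] * out$discrepancy[pre]
  } else {
    # ratio form needs the pre-base level at the base year
    ratio_tab <- series |>
      filter(.data$year == base_year) |>
      select(all_of(key), base_value = "value") |>
      left_join(base_discrepancy, by = key) |>
      mutate(discrepancy = dplyr::coalesce(.data$discrepancy, 0),
             ratio = .data$base_value /
               pmax(.data$base_value - .data$discrepancy, 1e-12)) |>
      select(all_of(key), "ratio")
    out <- out |> left_join(ratio_tab, by = key)
    adj <- out$value[pre] * out$ratio[pre]^out$w[pre]
  }
  floored <- sum(adj < 0)
  if (floored > 0) {
    inform(paste0("intercensal blend floored ", floored,
                  " cell(s) at zero"))
    adj <- pmax(adj, 0)
  }
  out$value[pre] <- adj
  out |> select(all_of(c("year", key)), "value")
}
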