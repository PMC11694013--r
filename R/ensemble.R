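#' Summarise simulation draws into point estimates and intervals
#'
#' Point estimate = mean of the draws; 95% uncertainty interval = 2.5th
#' to 97.5th percentile, with percentiles computed by linear
#' interpolation between order statistics (`quantile` type 7).  Respects
#' existing `dplyr` groups, summarising each group's draws separately.
#'
#' @param data A (possibly grouped) data frame of draws.
#' @param value_col Name of the draw column.
#' @param level Interval coverage (default 0.95).
#' @return One row per group: `mean`, `lower`, `upper`, `n_sims`.
#' @examples
#' summarize_ensemble(tibble::tibble(value = 1:1000))
#' @export
summarize_ensemble <- function(data, value_col = "value", level = 0.95) {
  alpha <- (1 - level) / 2
  out <- data |>
    summarise(
      n_sims = dplyr::n(),
      mean = mean(.data[[value_col]]),
      lower = quantile(.data[[value_col]], alpha, type = 7, names = FALSE),
      upper = quantile(.data[[value_col]], 1 - alpha, type = 7,
                       names = FALSE),
      .groups = "drop"
    ) |>
    relocate("mean", "lower", "upper", .before = "n_sims")
  if (any(out$n_sims < 2)) {
    abort("each group must contain at least two draws to summarise")
  }
  out
}

#' Pool deaths and population to America-level mortality rates
#'
#' Sums deaths and population over counties and races within each
#' America, then divides: the rate is the pooled-count rate, not an
#' average of county rates.  Errors if any pooled cell has deaths but no
#' population; cells with neither get rate 0 with a warning.
#'
#' @param deaths Death tibble with `value` and, optionally, `sim`.
#' @param population Population tibble with `value` (no `sim`).
#' @param assignments America assignment table from
#'   [classify_americas()].
#' @return Tibble keyed (america_id, year, age_group, sex\[, sim\]) with
#'   `deaths`, `population`, `m`.
#' @export
mortality_rates <- function(deaths, population, assignments) {
  has_sim <- "sim" %in% names(deaths)
  key <- c("america_id", "year", "age_group", "sex",
           if (has_sim) "sim")
  d <- deaths |>
    inner_join(assignments, by = c("county_id", "race")) |>
    group_by(across(all_of(key))) |>
    summarise(deaths = sum(.data$value), .groups = "drop")
  p <- population |>
    inner_join(assignments, by = c("county_id", "race")) |>
    group_by(across(all_of(setdiff(key, "sim")))) |>
    summarise(population = sum(.data$value), .groups = "drop")
  out <- d |> left_join(p, by = setdiff(key, "sim"))
  if (any(is.na(out$population) | (out$population == 0 & out$deaths > 0))) {
    abort("deaths present in a cell with zero population")
  }
  if (any(out$population == 0)) {
    warn("cells with zero population and zero deaths get rate 0")
  }
  out |>
    mutate(m = ifelse(.data$population > 0,
                      .data$deaths / .data$population, 0))
}

#' Life expectancy quantities across an ensemble of simulations
#'
#' Builds an abridged life table per (America, year, sex, simulation)
#' from pooled mortality rates, computes life expectancy at birth,
#' partial life expectancies for 0-4, 5-24, 25-44, 45-64 and 65-84, and
#' remaining life expectancy at 85, and summarises each across
#' simulations (mean and 95% uncertainty interval).  `sex = "both"`
#' pools the sexes before building the table.
#'
#' @param rates Output of [mortality_rates()] (with `sim`), or a death
#'   and population pair via `deaths`/`population`/`assignments`.
#' @param sexes Which reporting sexes to produce: subset of
#'   `c("both", "female", "male")`.
#' @param terminal_strategy,growth_rate Passed to the life-table engine.
#' @return Tibble (america_id, year, sex, quantity, mean, lower, upper,
#'   n_sims) with quantity in `e0`, `ple_0_4`, ..., `ple_65_84`, `e85`.
#' @export
life_expectancy_table <- function(rates,
                                  sexes = c("both", "female", "male"),
                                  terminal_strategy = "constant_hazard",
                                  growth_rate = 0) {
  sexes <- match.arg(sexes, several.ok = TRUE)
  schema <- age_schema()
  pieces <- lapply(sexes, function(sx) {
    r <- if (sx == "both") {
      rates |>
        group_by(.data$america_id, .data$year, .data$age_group, .data$sim) |>
        summarise(deaths = sum(.data$deaths),
                  population = sum(.data$population), .groups = "drop")
    } else {
      rates |> filter(.data$sex == sx)
    }
    r <- r |> mutate(m = .data$deaths / pmax(.data$population, 1e-12))
    draws <- le_draws(r, schema, terminal_strategy, growth_rate)
    draws$sex <- sx
    draws
  })
  bind_rows(pieces) |>
    group_by(.data$america_id, .data$year, .data$sex, .data$quantity) |>
    summarize_ensemble(value_col = "value") |>
    arrange(.data$america_id, .data$year, .data$sex, .data$quantity)
}

# draws of e0 / partial LEs / e85 per (america, year, sim) from a pooled
# rate table; vectorised through the matrix life-table engine
le_draws <- function(r, schema, terminal_strategy, growth_rate) {
  r <- r |> arrange(.data$america_id, .data$year, .data$sim, .data$age_group)
  col_key <- r |> distinct(.data$america_id, .data$year, .data$sim)
  k <- nrow(schema)
  m_mat <- matrix(0, nrow = k, ncol = nrow(col_key))
  ai <- match(r$age_group, schema$age_group)
  ci <- match(paste(r$america_id, r$year, r$sim),
              paste(col_key$america_id, col_key$year, col_key$sim))
  m_mat[cbind(ai, ci)] <- r$m
  eng <- life_table_engine(m_mat, schema,
                           terminal_strategy = terminal_strategy,
                           growth_rate = growth_rate)
  ranges <- list(ple_0_4 = c(0, 5), ple_5_24 = c(5, 25),
                 ple_25_44 = c(25, 45), ple_45_64 = c(45, 65),
                 ple_65_84 = c(65, 85))
  qs <- c(list(e0 = eng$e[1, ], e85 = eng$e[k, ]),
          lapply(ranges, function(rg) engine_partial_le(eng, rg[1], rg[2])))
  bind_rows(lapply(names(qs), function(nm) {
    out <- col_key
    out$quantity <- nm
    out$value <- qs[[nm]]
    out
  }))
}
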