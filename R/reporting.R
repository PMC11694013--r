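#' Published reference estimates
#'
#' Transcribed point estimates (with 95% uncertainty intervals) of life
#' expectancy at birth for the ten Americas in 2000, 2010, 2019, 2020
#' and 2021, and the 2021 population accounting of the ten Americas,
#' from the published national analysis these methods operationalise.
#' They give the reporting operations a fixed, paper-anchored surface to
#' work against; the package cannot re-estimate them because the
#' underlying vital-statistics microdata are restricted.
#'
#' @return `load_published_life_expectancy()`: tibble `america_id`,
#'   `label`, `year`, `mean`, `lower`, `upper` (years).
#'   `load_published_americas()`: tibble with county counts and 2021
#'   populations (millions) per America; the printed national total is
#'   attached as attribute `national_population_millions` (332.64).
#' @export
load_published_life_expectancy <- function() {
  readr::read_csv(system.file("extdata", "published_life_expectancy.csv",
                              package = "tenamericas", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' @rdname load_published_life_expectancy
#' @export
load_published_americas <- function() {
  out <- readr::read_csv(system.file("extdata", "published_americas.csv",
                                     package = "tenamericas",
                                     mustWork = TRUE),
                         show_col_types = FALSE)
  attr(out, "national_population_millions") <- 332.64
  out
}

#' Population share of an America
#'
#' Percentage of the printed national population belonging to one
#' America in 2021.
#'
#' @param table Output of [load_published_americas()] (or any tibble
#'   with `america_id` and `population_2021_millions`).
#' @param america America id (1-10).
#' @return Share in percent.
#' @examples
#' america_population_share(load_published_americas(), 2)
#' @export
america_population_share <- function(table, america) {
  total <- attr(table, "national_population_millions") %||%
    sum(table$population_2021_millions)
  pop <- table$population_2021_millions[table$america_id == america]
  if (length(pop) != 1) abort("america not found in table")
  100 * pop / total
}

check_year_column <- function(grid, year) {
  col <- grid |> filter(.data$year == !!year)
  missing <- setdiff(1:10, col$america_id)
  if (length(missing) > 0) {
    abort(paste0("year ", year, " is missing America(s): ",
                 paste(missing, collapse = ", ")))
  }
  col
}

#' Gap between the highest and lowest life expectancy
#'
#' Maximum minus minimum point estimate across the ten Americas in one
#' year, with the Americas attaining them.  Ties are broken by the lower
#' America id; all tied ids are listed.
#'
#' @param grid Life-expectancy grid: `america_id`, `year`, and a point
#'   estimate column.
#' @param year Calendar year.
#' @param value_col Point estimate column name (default `"mean"`).
#' @return One-row tibble: `year`, `gap`, `max`, `min`, `america_max`,
#'   `america_min`, `america_max_all`, `america_min_all`.
#' @examples
#' compute_gap(load_published_life_expectancy(), 2021)
#' @export
compute_gap <- function(grid, year, value_col = "mean") {
  col <- check_year_column(grid, year)
  v <- col[[value_col]]
  mx <- max(v); mn <- min(v)
  amax <- sort(col$america_id[v == mx]); amin <- sort(col$america_id[v == mn])
  tibble(year = year, gap = mx - mn, max = mx, min = mn,
         america_max = amax[1], america_min = amin[1],
         america_max_all = paste(amax, collapse = ","),
         america_min_all = paste(amin, collapse = ","))
}

#' Change in life expectancy over a period
#'
#' @param grid Life-expectancy grid (see [compute_gap()]).
#' @param america America id.
#' @param year_from,year_to Period endpoints.
#' @param value_col Point estimate column name.
#' @return Change in years, `value(year_to) - value(year_from)`.
#' @examples
#' compute_change(load_published_life_expectancy(), 6, 2000, 2010)
#' @export
compute_change <- function(grid, america, year_from, year_to,
                           value_col = "mean") {
  pick <- function(yr) {
    v <- grid[[value_col]][grid$america_id == america & grid$year == yr]
    if (length(v) != 1) {
      abort(paste0("no value for America ", america, " in ", yr))
    }
    v
  }
  pick(year_to) - pick(year_from)
}

#' Rank the Americas by life expectancy in a year
#'
#' Dense descending ranking (1 = highest).  Tied Americas share the
#' lower (better) rank number and are flagged.
#'
#' @inheritParams compute_gap
#' @return Tibble `america_id`, `value`, `rank`, `tied`, sorted by rank.
#' @examples
#' rank_americas(load_published_life_expectancy(), 2021)
#' @export
rank_americas <- function(grid, year, value_col = "mean") {
  col <- check_year_column(grid, year)
  v <- col[[value_col]]
  rk <- match(-v, sort(unique(-v)))  # dense rank, descending
  tibble(america_id = col$america_id, value = v, rank = rk,
         tied = duplicated(v) | duplicated(v, fromLast = TRUE)) |>
    arrange(.data$rank, .data$america_id)
}

#' Headline disparity statistics from a life-expectancy grid
#'
#' Per year: the max/min gap and the full ranking; per America and
#' consecutive year pair: the change in years.
#'
#' @inheritParams compute_gap
#' @return List of class `disparity_report` with tibbles `gaps`,
#'   `ranks`, `changes`.
#' @export
disparity_report <- function(grid, value_col = "mean") {
  years <- sort(unique(grid$year))
  gaps <- bind_rows(lapply(years, compute_gap, grid = grid,
                           value_col = value_col))
  ranks <- bind_rows(lapply(years, function(yr) {
    rank_americas(grid, yr, value_col) |> mutate(year = yr)
  }))
  changes <- if (length(years) > 1) {
    tidyr::expand_grid(america_id = sort(unique(grid$america_id)),
                       i = seq_len(length(years) - 1)) |>
      mutate(year_from = years[.data$i], year_to = years[.data$i + 1],
             i = NULL) |>
      rowwise() |>
      mutate(change = compute_change(grid, .data$america_id,
                                     .data$year_from, .data$year_to,
                                     value_col)) |>
      ungroup()
  } else {
    tibble()
  }
  structure(list(gaps = gaps, ranks = ranks, changes = changes),
            class = "disparity_report")
}

#' @export
print.disparity_report <- function(x, ...) {
  cat("Disparity report over", nrow(x$gaps), "year(s)\n\nGaps:\n")
  print(x$gaps |> select("year", "gap", "america_max", "america_min"))
  if (nrow(x$changes) > 0) {
    cat("\nLargest single-period changes:\n")
    print(x$changes |> arrange(dplyr::desc(abs(.data$change))) |> head(5))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding matching the published tables (base `round()` uses
#' round-half-even).  Internal computation is never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @examples
#' round_half_up(0.15, 1)  # 0.2
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
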