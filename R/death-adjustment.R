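#' Single-race composition shares
#'
#' Shares of each single race within a cell, computed from a population
#' table; used to reallocate "Two or More Races" deaths and population
#' onto the single-race categories.
#'
#' @param population Population tibble (`value` column); `multirace`
#'   rows are ignored.
#' @param by Key columns defining a cell.
#' @return Tibble of `by` columns plus `race` and `share` (shares sum to
#'   1 within each cell).
#' @export
race_composition <- function(population,
                             by = c("year", "county_id", "age_group", "sex")) {
  population |>
    filter(.data$race != "multirace") |>
    group_by(across(all_of(by))) |>
    mutate(share = .data$value / sum(.data$value)) |>
    ungroup() |>
    select(all_of(by), "race", "share")
}

#' Bridge multiple-race deaths onto single-race categories
#'
#' Deaths recorded in a `multirace` category are reallocated to the
#' single races in proportion to the local single-race composition, then
#' added to the single-race counts; the grand total is conserved
#' exactly.  This mirrors race bridging: mapping multiple-race reports
#' onto single-race categories for consistency with years in which only
#' a single race could be recorded.
#'
#' @param deaths Death tibble (`value` column) possibly containing
#'   `multirace` rows.
#' @param composition Output of [race_composition()] on the matching
#'   population (same `by` key).
#' @param by Key columns defining a cell.
#' @return The death table without `multirace` rows, totals conserved.
#' @export
bridge_multirace_deaths <- function(deaths, composition,
                                    by = c("year", "county_id",
                                           "age_group", "sex")) {
  multi <- deaths |> filter(.data$race == "multirace", .data$value > 0)
  single <- deaths |> filter(.data$race != "multirace")
  if (nrow(multi) == 0) return(single)

  alloc <- multi |>
    select(all_of(by), multi_value = "value") |>
    left_join(composition, by = by, relationship = "many-to-many")
  if (anyNA(alloc$share)) {
    abort("multirace deaths present in cells with no single-race composition")
  }
  alloc <- alloc |>
    mutate(value = .data$multi_value * .data$share) |>
    select(all_of(by), "race", "value")
  bind_rows(single, alloc) |>
    group_by(across(all_of(c(by, "race")))) |>
    summarise(value = sum(.data$value), .groups = "drop")
}

# log-normal parameters matching an arithmetic mean and SD
lnorm_params <- function(mean, se) {
  if (any(mean <= 0)) abort("ratio mean must be strictly positive")
  if (any(se < 0)) abort("ratio se must be non-negative")
  sigma2 <- log(1 + se^2 / mean^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Simulate misclassification-ratio draws from a log-normal
#'
#' For each ratio row, draws `n_sims` values from a log-normal whose
#' arithmetic mean equals the reported ratio and whose arithmetic SD
#' equals the reported SE (moment matching:
#' \eqn{\sigma^2 = \log(1 + se^2/mean^2)},
#' \eqn{\mu = \log(mean) - \sigma^2/2}).  A zero SE yields draws exactly
#' equal to the mean.
#'
#' @param ratios Tibble with columns `race`, `dimension`, `level`,
#'   `mean`, `se` (as from [derive_misclassification_ratios()]).
#' @param n_sims Number of draws per ratio (default 1000).
#' @param seed Integer seed.
#' @return The input columns plus `sim` (1..n_sims) and `draw` (> 0), in
#'   long format.
#' @export
draw_ratios_lognormal <- function(ratios, n_sims = 1000, seed = 1L) {
  p <- lnorm_params(ratios$mean, ratios$se)
  set.seed(seed)
  k <- nrow(ratios)
  draws <- matrix(rlnorm(k * n_sims,
                         meanlog = rep(p$meanlog, each = n_sims),
                         sdlog = rep(p$sdlog, each = n_sims)),
                  nrow = n_sims)
  degenerate <- ratios$se == 0
  if (any(degenerate)) {
    draws[, degenerate] <- rep(ratios$mean[degenerate], each = n_sims)
  }
  ratios |>
    mutate(.row = dplyr::row_number()) |>
    tidyr::expand_grid(sim = seq_len(n_sims)) |>
    mutate(draw = draws[cbind(.data$sim, .data$.row)], .row = NULL)
}

#' Combine ratio draws across dimensions
#'
#' Combines per-dimension misclassification ratios into a single ratio
#' per stratum and simulation as multiplicative deviations from the
#' race-level overall ratio:
#' \deqn{combined_s = overall_s \prod_d component_{d,s} / overall_s.}
#' If every component equals the overall ratio the combination is the
#' overall ratio; a single deviating dimension passes through unchanged.
#'
#' @param draws Long draw table from [draw_ratios_lognormal()], holding
#'   an `overall` dimension plus any of `age_sex`, `region`, `density`.
#' @param strata Tibble of target strata with columns `race` and one
#'   column per non-overall dimension present in `draws` (named
#'   `age_sex`, `region`, `density_level`), identifying the applicable
#'   level.
#' @return `strata` expanded by `sim` with a `ratio` column.
#' @export
combine_ratio_dimensions <- function(draws, strata) {
  dims <- setdiff(unique(draws$dimension), "overall")
  if (!"overall" %in% draws$dimension) {
    abort("draws must include an 'overall' dimension")
  }
  level_col <- c(age_sex = "age_sex", region = "region",
                 density = "density_level")
  overall <- draws |>
    filter(.data$dimension == "overall") |>
    select("race", "sim", overall = "draw")
  out <- strata |>
    tidyr::expand_grid(sim = sort(unique(draws$sim))) |>
    left_join(overall, by = c("race", "sim"))
  if (anyNA(out$overall)) {
    abort("missing overall ratio draws for some races")
  }
  out$ratio <- out$overall
  for (dim in dims) {
    col <- level_col[[dim]]
    if (!col %in% names(strata)) {
      abort(paste0("strata lack a '", col, "' column for dimension '",
                   dim, "'"))
    }
    comp <- draws |>
      filter(.data$dimension == dim) |>
      select("race", level = "level", "sim", comp = "draw")
    out <- out |>
      left_join(comp, by = stats::setNames(c("race", "level", "sim"),
                                           c("race", col, "sim")))
    if (anyNA(out$comp)) {
      bad <- out |> filter(is.na(.data$comp)) |> slice(1)
      abort(paste0("no '", dim, "' ratio draws for stratum race=",
                   bad$race, ", level=", bad[[col]]))
    }
    out$ratio <- out$ratio * out$comp / out$overall
    out$comp <- NULL
  }
  out |> select(-"overall")
}

#' Apply misclassification ratios and rescale to conserve totals
#'
#' Multiplies each cell's recorded deaths by its combined ratio draw,
#' then rescales within every (year, county, age, sex, simulation)
#' stratum by `raw total / corrected total`, so the race-summed number
#' of deaths in each stratum is unchanged by the correction.
#'
#' @param raw_deaths Tibble with stratum keys, `race` and `value`
#'   (recorded deaths).
#' @param combined_ratios Output of [combine_ratio_dimensions()] joined
#'   to cells: must contain the stratum keys, `race`, `sim`, `ratio`.
#' @param by Stratum key columns within which totals are conserved.
#' @return Tibble of stratum keys, `race`, `sim`, `value` (corrected,
#'   real-valued).
#' @export
apply_and_rescale <- function(raw_deaths, combined_ratios,
                              by = c("year", "county_id", "age_group",
                                     "sex")) {
  join_cols <- intersect(names(combined_ratios),
                         c(by, "race"))
  out <- raw_deaths |>
    inner_join(combined_ratios |> select(all_of(join_cols), "sim", "ratio"),
               by = join_cols, relationship = "many-to-many") |>
    mutate(corrected = .data$value * .data$ratio) |>
    group_by(across(all_of(c(by, "sim"))))
  sums <- out |>
    summarise(raw_total = sum(.data$value),
              corr_total = sum(.data$corrected), .groups = "drop")
  if (any(sums$corr_total == 0 & sums$raw_total > 0)) {
    abort("corrected deaths sum to zero in a stratum with raw deaths")
  }
  out |>
    mutate(scale = sum(.data$value) / sum(.data$corrected),
           scale = ifelse(is.finite(.data$scale), .data$scale, 1)) |>
    ungroup() |>
    mutate(value = .data$corrected * .data$scale) |>
    select(all_of(by), "race", "sim", "value")
}

# deterministic per-simulation sub-seed from a root seed
sim_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483646L) + 1L
}

#' Add Poisson stochastic variation to a simulated death table
#'
#' Replaces each (cell, simulation) value by one Poisson draw with the
#' value as its rate, representing the stochastic variation of observed
#' death counts.  Each simulation index uses an independent stream
#' derived from the root seed, so results do not depend on row order
#' within a simulation block and are reproducible under parallel
#' execution by simulation.
#'
#' @param death_table Tibble with `sim` and non-negative `value`.
#' @param seed Root integer seed.
#' @return The table with `value` replaced by integer Poisson draws.
#' @export
poisson_perturb <- function(death_table, seed) {
  if (any(death_table$value < 0)) abort("Poisson rates must be non-negative")
  out <- death_table
  for (s in sort(unique(out$sim))) {
    idx <- which(out$sim == s)
    set.seed(sim_seed(seed, s))
    out$value[idx] <- rpois(length(idx), out$value[idx])
  }
  out
}
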