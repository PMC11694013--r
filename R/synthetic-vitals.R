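#' Generate synthetic county attributes
#'
#' Draws a table of counties with every attribute the ten-Americas
#' definitions consume: state, Rural-Urban Continuum Code (1-9),
#' Black-White dissimilarity index (computed from simulated subunit
#' counts with [dissimilarity_index()]), the NHPI share of the combined
#' Asian+NHPI population, race-specific incomes per capita centred so a
#' configurable fraction of counties falls below the $32,363 low-income
#' threshold, and regional membership flags (Appalachia and Lower
#' Mississippi Valley sampled with state-specific probabilities; Deep
#' South deterministic by state).
#'
#' The generated set is checked to populate all ten Americas; an error
#' naming the empty Americas is raised otherwise (raise `n_counties`).
#'
#' @param config A [sim_config()].
#' @return A tibble of county attributes, one row per county, including
#'   a `region` (census region) column and a relative `size_weight` used
#'   by the population generator.
#' @export
generate_counties <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_counties
  county_id <- sprintf("c%04d", seq_len(n))
  state <- sample(state_codes, n, replace = TRUE)
  rucc <- sample(1:9, n, replace = TRUE)

  # dissimilarity from simulated tract-level weights; a share of counties
  # gets strongly clustered Black settlement patterns so high-segregation
  # metros exist
  alpha_b <- sample(c(0.15, 0.8, 3), n, replace = TRUE,
                    prob = c(0.35, 0.35, 0.3))
  dis <- vapply(seq_len(n), function(i) {
    b <- rgamma(config$tracts_per_county, shape = alpha_b[i])
    w <- rgamma(config$tracts_per_county, shape = 3)
    dissimilarity_index(b, w)
  }, numeric(1))

  nhpi_share <- rbeta(n, 2, 8)

  sdlog <- config$income_sdlog
  mulog <- log(income_threshold) - stats::qnorm(config$low_income_fraction) * sdlog
  incomes <- lapply(config$races, function(r) exp(rnorm(n, mulog, sdlog)))
  names(incomes) <- paste0("income_", config$races)

  appalachia <- runif(n) < unname(appalachia_probs[state] %|0|% 0)
  lmv <- runif(n) < unname(lmv_probs[state] %|0|% 0)
  deep_south <- state %in% deep_south_states

  size_weight <- exp(rnorm(n, 0, 0.8)) * c(8, 4, 2, 1.5, 1, 1, 0.7, 0.5, 0.4)[rucc]

  attrs <- tibble(
    county_id = county_id, state = state,
    region = unname(census_region_map[state]), rucc = as.integer(rucc),
    dissimilarity_index = dis, nhpi_share = nhpi_share,
    appalachia = appalachia, lower_mississippi_valley = lmv,
    deep_south = deep_south, size_weight = size_weight
  ) |>
    bind_cols(as_tibble(incomes))

  counts <- tryCatch(
    validate_partition(classify_americas(attrs, config$races)),
    error = function(e) {
      abort(paste0("synthetic county set does not populate all ten ",
                   "Americas (increase n_counties): ", conditionMessage(e)))
    })
  attrs
}

# named-lookup with 0 default for states without a flag probability
`%|0|%` <- function(x, default) ifelse(is.na(x), default, x)

#' Generate a synthetic population series
#'
#' Builds positive real-valued population counts for every
#' (year, county, age group, sex, race) cell.  Within a county the race
#' mix is Dirichlet-distributed around national shares, the age profile
#' declines smoothly with age, sexes split evenly, and each county-race
#' series grows at a small constant rate so the series is smooth in time
#' - except at `discontinuity_year`, where a census-base change
#' multiplies each county-race series by `1 +/- discontinuity_scale`
#' (sign random per series) and a "Two or More Races" (`multirace`)
#' category appears, carved out of the single-race cells.
#'
#' @param config A [sim_config()].
#' @param counties Output of [generate_counties()].
#' @return A tibble `year`, `county_id`, `age_group`, `sex`, `race`,
#'   `value` (persons; real-valued).
#' @export
generate_population <- function(config, counties) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  schema <- age_schema()
  races <- config$races
  n <- nrow(counties)

  national_mix <- c(aian = 0.03, asian_nhpi = 0.06, black = 0.13,
                    latino = 0.18, white = 0.60)[races]
  mix <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(length(races), shape = national_mix * 25)
    g / sum(g)
  }, numeric(length(races))))
  colnames(mix) <- races

  age_profile <- schema$age_width
  age_profile[!is.finite(age_profile)] <- 5
  age_profile <- age_profile * exp(-0.012 * age_midpoints(schema))
  age_profile <- age_profile / sum(age_profile)

  growth <- rnorm(n, 0.004, 0.004)
  base_pop <- counties$size_weight / mean(counties$size_weight) * 60000
  jump_sign <- matrix(sample(c(-1, 1), n * length(races), replace = TRUE),
                      nrow = n, dimnames = list(NULL, races))

  grid <- tidyr::expand_grid(
    county_idx = seq_len(n),
    age_idx = seq_len(nrow(schema)),
    sex = c("female", "male"),
    race = races
  )
  grid$year <- NA_integer_  # filled per year below

  per_year <- lapply(config$years, function(yr) {
    g <- grid
    g$year <- yr
    base <- base_pop[g$county_idx] *
      mix[cbind(g$county_idx, match(g$race, races))] *
      age_profile[g$age_idx] * 0.5 *
      (1 + growth[g$county_idx])^(yr - min(config$years))
    if (yr >= config$discontinuity_year && config$discontinuity_scale > 0) {
      base <- base * (1 + config$discontinuity_scale *
                        jump_sign[cbind(g$county_idx, match(g$race, races))])
    }
    g$value <- pmax(base, 1e-6)
    if (yr >= config$discontinuity_year && config$multirace_share > 0) {
      single <- g
      single$value <- single$value * (1 - config$multirace_share)
      multi <- g |>
        group_by(.data$county_idx, .data$age_idx, .data$sex, .data$year) |>
        summarise(value = sum(.data$value) * config$multirace_share,
                  .groups = "drop") |>
        mutate(race = "multirace")
      bind_rows(single, multi)
    } else {
      g
    }
  })

  bind_rows(per_year) |>
    mutate(county_id = counties$county_id[.data$county_idx],
           age_group = schema$age_group[.data$age_idx]) |>
    select("year", "county_id", "age_group", "sex", "race", "value") |>
    arrange(.data$year, .data$county_id, .data$age_group, .data$sex,
            .data$race)
}

# hazard at the group midpoint for each row of a (race, age) keyed table
gompertz_hazard <- function(race, age_mid, params, male = FALSE,
                            male_hazard_ratio = 1) {
  i <- match(race, params$race)
  if (anyNA(i)) abort("hazard parameters missing for some race labels")
  h <- params$makeham[i] + params$level[i] * exp(params$slope[i] * age_mid)
  h * ifelse(male, male_hazard_ratio, 1)
}

#' Simulate death counts from a population table
#'
#' Draws integer deaths per cell from a Poisson distribution with rate
#' `population x hazard(age midpoint)`, where the hazard is
#' Gompertz-Makeham \eqn{h(x) = c + a e^{b x}} with race-specific
#' parameters and a constant male multiplier.  The race in the output is
#' the decedent's self-reported (true) race; certificate misreporting is
#' applied separately by [apply_misreporting()].
#'
#' @param population Population tibble from [generate_population()].
#' @param gompertz_params Parameter tibble (`race`, `level`, `slope`,
#'   `makeham`); see [default_gompertz_params()].
#' @param seed Integer seed.
#' @param male_hazard_ratio Hazard multiplier for males.
#' @return The population table with a `deaths` column (integer) in
#'   place of `value`.
#' @export
simulate_deaths <- function(population, gompertz_params, seed,
                            male_hazard_ratio = 1.4) {
  schema <- age_schema()
  mid <- age_midpoints(schema)[match(population$age_group, schema$age_group)]
  h <- gompertz_hazard(population$race, mid, gompertz_params,
                       male = population$sex == "male",
                       male_hazard_ratio = male_hazard_ratio)
  rate <- population$value * h
  if (any(rate > 2^31)) {
    abort("death rate overflow: population x hazard exceeds integer range")
  }
  set.seed(seed)
  population |>
    mutate(deaths = rpois(length(rate), rate), value = NULL)
}

# allocate integer counts across destinations with given row of
# probabilities, vectorised over cells via sequential binomial thinning
allocate_multinomial <- function(counts, probs) {
  k <- length(probs)
  out <- matrix(0L, nrow = length(counts), ncol = k)
  remaining <- counts
  p_left <- 1
  for (j in seq_len(k - 1L)) {
    p <- if (p_left > 0) probs[j] / p_left else 0
    draw <- rbinom(length(remaining), remaining, max(0, min(p, 1)))
    out[, j] <- draw
    remaining <- remaining - draw
    p_left <- p_left - probs[j]
  }
  out[, k] <- remaining
  out
}

#' Apply certificate race misreporting to simulated deaths
#'
#' Each death with self-reported race r is recorded on the certificate
#' as race s with probability `misreport_matrix[r, s]`.  Deaths are
#' reallocated between races within each (year, county, age, sex)
#' stratum; stratum totals are conserved exactly.  A `multirace`
#' category, if present, passes through unchanged.
#'
#' @param deaths Output of [simulate_deaths()] (column `deaths`, race =
#'   self-reported).
#' @param misreport_matrix Row-stochastic matrix over the race labels
#'   present (excluding `multirace`).
#' @param seed Integer seed.
#' @return A tibble keyed (year, county_id, age_group, sex, race) with
#'   columns `deaths_true` and `deaths_recorded`.
#' @export
apply_misreporting <- function(deaths, misreport_matrix, seed) {
  races <- rownames(misreport_matrix)
  if (is.null(races) ||
      any(abs(rowSums(misreport_matrix) - 1) > 1e-12) ||
      any(misreport_matrix < 0)) {
    abort("misreport_matrix must be row-stochastic with race dimnames")
  }
  set.seed(seed)
  wide <- deaths |>
    tidyr::pivot_wider(names_from = "race", values_from = "deaths",
                       values_fill = 0L)
  present <- intersect(races, names(wide))
  rec <- matrix(0L, nrow = nrow(wide), ncol = length(present),
                dimnames = list(NULL, present))
  for (r in present) {
    alloc <- allocate_multinomial(wide[[r]],
                                  misreport_matrix[r, present])
    rec <- rec + alloc
  }
  key_cols <- setdiff(names(wide), c(races, "multirace"))
  long_true <- deaths |> rename(deaths_true = "deaths")
  long_rec <- bind_cols(wide[key_cols], as_tibble(rec)) |>
    tidyr::pivot_longer(all_of(present), names_to = "race",
                        values_to = "deaths_recorded")
  if ("multirace" %in% names(wide)) {
    long_rec <- bind_rows(long_rec,
                          bind_cols(wide[key_cols],
                                    tibble(race = "multirace",
                                           deaths_recorded = wide$multirace)))
  }
  long_true |>
    left_join(long_rec, by = c(key_cols, "race")) |>
    mutate(deaths_recorded = dplyr::coalesce(.data$deaths_recorded, 0L))
}

# broad age-sex bands used as misclassification-ratio cells
age_sex_band <- function(age_group, sex) {
  schema <- age_schema()
  start <- schema$age_start[match(age_group, schema$age_group)]
  band <- cut(start, breaks = c(-1, 24, 64, Inf),
              labels = c("0-24", "25-64", "65+"))
  paste(band, sex, sep = ".")
}

#' Co-ethnic density terciles
#'
#' For Latino and AIAN populations, counties are split into terciles of
#' the share of the county population belonging to the group (a co-ethnic
#' density measure); misclassification is known to vary with this
#' concentration for those groups.  Other races get a single `all`
#' stratum.
#'
#' @param population Population table (any one year is used: the latest).
#' @param races Race labels to stratify.
#' @return Tibble `county_id`, `race`, `density_level` in
#'   `{low, mid, high, all}`.
#' @export
county_density_terciles <- function(population, races = race_labels()) {
  yr <- max(population$year)
  shares <- population |>
    filter(.data$year == yr, .data$race != "multirace") |>
    group_by(.data$county_id) |>
    mutate(total = sum(.data$value)) |>
    group_by(.data$county_id, .data$race) |>
    summarise(share = sum(.data$value) / first(.data$total),
              .groups = "drop")
  dens_races <- intersect(c("latino", "aian"), races)
  out <- tidyr::expand_grid(county_id = unique(shares$county_id),
                            race = races) |>
    mutate(density_level = "all")
  for (r in dens_races) {
    s <- shares |> filter(.data$race == r)
    cuts <- quantile(s$share, c(1 / 3, 2 / 3), type = 7)
    lev <- cut(s$share, breaks = c(-Inf, cuts, Inf),
               labels = c("low", "mid", "high"))
    idx <- match(paste(s$county_id, r), paste(out$county_id, out$race))
    out$density_level[idx] <- as.character(lev)
  }
  out
}

#' Derive misclassification ratios from true and recorded tabulations
#'
#' For each race and each requested dimension cell, the ratio of deaths
#' tabulated by self-reported race to deaths tabulated by
#' certificate-recorded race.  Multiplying recorded-race death counts by
#' this ratio corrects, at the population level, the net effect of
#' misreporting.  A delta-method standard error for a ratio of Poisson
#' totals, `se = ratio * sqrt(1/numerator + 1/denominator)`, is attached.
#' Cells with zero recorded deaths are dropped with a warning.
#'
#' Dimensions: `overall` (race only), `age_sex` (broad age bands by
#' sex), `region` (census region), `density` (co-ethnic density
#' terciles, Latino and AIAN only).
#'
#' @param batches Output of [apply_misreporting()].
#' @param counties County attributes (for `region`).
#' @param density Tercile table from [county_density_terciles()], or
#'   `NULL` to use a single stratum per race.
#' @param dimensions Character subset of
#'   `c("overall", "age_sex", "region", "density")`.
#' @return Tibble `race`, `dimension`, `level`, `mean`, `se`.
#' @export
derive_misclassification_ratios <- function(batches, counties,
                                            density = NULL,
                                            dimensions = c("overall",
                                                           "age_sex",
                                                           "region",
                                                           "density")) {
  dimensions <- match.arg(dimensions, several.ok = TRUE)
  if (sum(batches$deaths_recorded) == 0) {
    abort("all recorded death counts are zero; cannot derive ratios")
  }
  d <- batches |>
    filter(.data$race != "multirace") |>
    left_join(counties |> select("county_id", "region"), by = "county_id")
  d$age_sex <- age_sex_band(d$age_group, d$sex)
  if (!is.null(density)) {
    d <- d |> left_join(density, by = c("county_id", "race"))
  } else {
    d$density_level <- "all"
  }

  one_dim <- function(dim) {
    lev <- switch(dim,
                  overall = rep("all", nrow(d)),
                  age_sex = d$age_sex,
                  region = d$region,
                  density = d$density_level)
    d |>
      mutate(level = lev) |>
      group_by(.data$race, .data$level) |>
      summarise(num = sum(.data$deaths_true),
                den = sum(.data$deaths_recorded), .groups = "drop") |>
      mutate(dimension = dim)
  }
  tab <- bind_rows(lapply(dimensions, one_dim))
  zero <- tab |> filter(.data$den == 0)
  if (nrow(zero) > 0) {
    warn(paste0("dropping ", nrow(zero),
                " ratio cell(s) with zero recorded deaths: ",
                paste(head(paste(zero$race, zero$dimension, zero$level,
                                 sep = "/"), 5), collapse = ", ")))
    tab <- tab |> filter(.data$den > 0)
  }
  tab |>
    mutate(mean = .data$num / .data$den,
           se = .data$mean * sqrt(1 / pmax(.data$num, 1) + 1 / .data$den)) |>
    select("race", "dimension", "level", "mean", "se")
}

#' Write the synthetic inputs to a directory as plain CSV
#'
#' Writes `county_attributes.csv`, `population.csv`, `deaths.csv`
#' (recorded tabulation), `misclassification_ratios.csv` and a
#' `config.yaml` capturing the generator parameters and seed.
#'
#' @param dir Output directory (created if needed).
#' @param config,counties,population,batches,ratios Generator outputs.
#' @return Invisibly, the directory path.
#' @export
write_synthetic_vitals <- function(dir, config, counties, population,
                                   batches, ratios) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(counties, file.path(dir, "county_attributes.csv"))
  readr::write_csv(population, file.path(dir, "population.csv"))
  readr::write_csv(batches |>
                     select(-"deaths_true") |>
                     rename(value = "deaths_recorded"),
                   file.path(dir, "deaths.csv"))
  readr::write_csv(ratios, file.path(dir, "misclassification_ratios.csv"))
  cfg <- config
  cfg$gompertz_params <- as.list(cfg$gompertz_params)
  cfg$misreport_matrix <- as.vector(cfg$misreport_matrix)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
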