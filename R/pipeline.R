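# ---- fast internal correction path ----------------------------------------
# The simulation-expanded correction is memory-heavy in long format, so the
# pipeline works on matrices: rows = death cells, columns = simulations,
# with integer index vectors mapping cells to ratio rows, conservation
# strata and output (America) groups.  The math is identical to
# combine_ratio_dimensions() + apply_and_rescale() and is cross-checked
# against them in the tests.

# draws_list: named list of matrices (rows keyed "race" or "race|level",
# cols = sims) for dimensions overall, age_sex, region, density
ratio_draw_matrices <- function(ratios, n_sims, seed) {
  p <- lnorm_params(ratios$mean, ratios$se)
  set.seed(seed)
  draws <- matrix(rlnorm(nrow(ratios) * n_sims,
                         meanlog = rep(p$meanlog, times = n_sims),
                         sdlog = rep(p$sdlog, times = n_sims)),
                  nrow = nrow(ratios))
  deg <- ratios$se == 0
  if (any(deg)) draws[deg, ] <- ratios$mean[deg]
  split_idx <- split(seq_len(nrow(ratios)), ratios$dimension)
  lapply(split_idx, function(ix) {
    m <- draws[ix, , drop = FALSE]
    rownames(m) <- paste(ratios$race[ix], ratios$level[ix], sep = "|")
    m
  })
}

# corrected deaths aggregated to output groups, as a matrix
# (n output groups x n_sims); cells must carry deaths plus index columns
correct_and_aggregate <- function(cells, draws, n_sims, n_out,
                                  block_size = 200) {
  out <- matrix(0, nrow = n_out, ncol = n_sims)
  raw_tot <- rowsum(cells$deaths, cells$stratum_i)
  blocks <- split(seq_len(n_sims),
                  ceiling(seq_len(n_sims) / block_size))
  for (blk in blocks) {
    R <- draws$age_sex[cells$r_a, blk, drop = FALSE] *
      draws$region[cells$r_g, blk, drop = FALSE] *
      draws$density[cells$r_d, blk, drop = FALSE] /
      draws$overall[cells$r_o, blk, drop = FALSE]^2
    corr <- cells$deaths * R
    corr_tot <- rowsum(corr, cells$stratum_i)
    scale <- as.vector(raw_tot) / corr_tot
    scale[!is.finite(scale)] <- 1
    # stratum_i is contiguous 1..K, and rowsum sorts numeric groups, so
    # row k of `scale` is stratum k
    corr <- corr * scale[cells$stratum_i, , drop = FALSE]
    agg <- rowsum(corr, cells$out_i)
    out[as.integer(rownames(agg)), blk] <- out[as.integer(rownames(agg)), blk] + agg
  }
  out
}

# index a vector of keys into the rows of a draw matrix
draw_row_index <- function(race, level, mat) {
  idx <- match(paste(race, level, sep = "|"), rownames(mat))
  if (anyNA(idx)) {
    abort(paste0("no ratio draws for stratum ",
                 paste(head(unique(paste(race, level)[is.na(idx)]), 3),
                       collapse = "; ")))
  }
  idx
}

# build the indexed cell table joining deaths to ratio keys and groups
build_cells <- function(deaths, counties, density, assignments, draws) {
  schema <- age_schema()
  d <- deaths |>
    left_join(counties |> select("county_id", "region"), by = "county_id") |>
    left_join(density, by = c("county_id", "race")) |>
    inner_join(assignments, by = c("county_id", "race"))
  d$age_sex <- age_sex_band(d$age_group, d$sex)
  stratum_key <- paste(d$year, d$county_id, d$age_group, d$sex)
  out_key <- paste(d$america_id, d$year, d$age_group, d$sex)
  out_levels <- sort(unique(out_key))
  list(
    cells = tibble(
      deaths = d$value,
      stratum_i = match(stratum_key, sort(unique(stratum_key))),
      out_i = match(out_key, out_levels),
      r_o = draw_row_index(d$race, "all", draws$overall),
      r_a = draw_row_index(d$race, d$age_sex, draws$age_sex),
      r_g = draw_row_index(d$race, d$region, draws$region),
      r_d = draw_row_index(d$race, d$density_level, draws$density)
    ),
    out_key = tibble(
      america_id = as.integer(sub(" .*", "", out_levels)),
      year = as.integer(vapply(strsplit(out_levels, " "),
                               `[`, "", 2)),
      age_group = vapply(strsplit(out_levels, " "), `[`, "", 3),
      sex = vapply(strsplit(out_levels, " "), `[`, "", 4)
    )
  )
}

# Poisson layer on an aggregated (groups x sims) matrix, one independent
# stream per simulation column
poisson_matrix <- function(mat, seed) {
  for (s in seq_len(ncol(mat))) {
    set.seed(sim_seed(seed, s))
    mat[, s] <- rpois(nrow(mat), mat[, s])
  }
  mat
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes every stage end to end on synthetic inputs: generate
#' counties, population and deaths; apply certificate race
#' misreporting; derive misclassification ratios; classify county-race
#' units into the ten Americas; harmonise the population series (Two or
#' More Races split, census-base blend); correct deaths with simulated
#' ratio draws, rescaling so stratum totals are conserved; add Poisson
#' stochastic variation; build abridged life tables per simulation; and
#' summarise life expectancy with 95% uncertainty intervals.
#'
#' @param config A [sim_config()].
#' @param n_sims Number of simulation draws (default 1000).
#' @param seed Root seed; defaults to `config$seed`.
#' @param sexes Reporting sexes, subset of `c("both", "female", "male")`.
#' @param correction Apply the misclassification correction (disable for
#'   diagnostics).
#' @param poisson Apply the Poisson stochastic-variation layer.
#' @param out_dir Optional directory; when given, writes
#'   `life_expectancy.csv`, `america_assignments.csv`,
#'   `misclassification_ratios.csv` and `manifest.json`.
#' @return A list of class `ten_americas_run`: `life_expectancy`
#'   (summarised grid), `assignments`, `ratios`, `counties`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), n_sims = 1000,
                         seed = config$seed,
                         sexes = "both",
                         correction = TRUE, poisson = TRUE,
                         out_dir = NULL) {
  counties <- generate_counties(config)
  population <- generate_population(config, counties)
  deaths_true <- simulate_deaths(population, config$gompertz_params,
                                 seed = seed + 1000L,
                                 male_hazard_ratio = config$male_hazard_ratio)
  batches <- apply_misreporting(deaths_true, config$misreport_matrix,
                                seed = seed + 2000L)
  density <- county_density_terciles(population, config$races)
  ratios <- derive_misclassification_ratios(batches, counties, density)
  assignments <- classify_americas(counties, config$races)
  validate_partition(assignments)

  # population harmonisation
  pop_single <- split_two_or_more_races(population)
  if (config$discontinuity_scale > 0 &&
      config$discontinuity_year > min(config$years) &&
      config$discontinuity_year <= max(config$years)) {
    disc <- estimate_base_discrepancy(pop_single, config$discontinuity_year)
    pop_adj <- intercensal_blend(pop_single, disc,
                                 config$discontinuity_year)
  } else {
    pop_adj <- pop_single
  }

  # recorded deaths, bridged onto single races
  recorded <- batches |>
    select("year", "county_id", "age_group", "sex", "race",
           value = "deaths_recorded")
  recorded <- bridge_multirace_deaths(recorded,
                                      race_composition(pop_adj))

  if (correction) {
    draws <- ratio_draw_matrices(ratios, n_sims, seed = seed + 3000L)
    built <- build_cells(recorded, counties, density, assignments, draws)
    agg <- correct_and_aggregate(built$cells, draws, n_sims,
                                 n_out = nrow(built$out_key))
  } else {
    base <- recorded |>
      inner_join(assignments, by = c("county_id", "race")) |>
      group_by(.data$america_id, .data$year, .data$age_group, .data$sex) |>
      summarise(deaths = sum(.data$value), .groups = "drop")
    built <- list(out_key = base |> select(-"deaths"))
    agg <- matrix(rep(base$deaths, n_sims), ncol = n_sims)
  }
  if (poisson) agg <- poisson_matrix(agg, seed = seed + 4000L)

  pop_agg <- pop_adj |>
    inner_join(assignments, by = c("county_id", "race")) |>
    group_by(.data$america_id, .data$year, .data$age_group, .data$sex) |>
    summarise(population = sum(.data$value), .groups = "drop")
  rates <- built$out_key |>
    mutate(.row = dplyr::row_number()) |>
    tidyr::expand_grid(sim = seq_len(n_sims)) |>
    mutate(deaths = agg[cbind(.data$.row, .data$sim)], .row = NULL) |>
    left_join(pop_agg, by = c("america_id", "year", "age_group", "sex"))
  if (any(is.na(rates$population))) {
    abort("stage lifetables: deaths present for cells with no population")
  }

  le <- life_expectancy_table(rates, sexes = sexes)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tenamericas")),
    seed = seed, n_sims = n_sims,
    n_counties = nrow(counties), years = range(config$years),
    correction = correction, poisson = poisson,
    rows = list(population = nrow(population),
                deaths = nrow(deaths_true),
                ratios = nrow(ratios),
                assignments = nrow(assignments),
                life_expectancy = nrow(le))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(le, file.path(out_dir, "life_expectancy.csv"))
    readr::write_csv(assignments,
                     file.path(out_dir, "america_assignments.csv"))
    readr::write_csv(ratios,
                     file.path(out_dir, "misclassification_ratios.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(life_expectancy = le, assignments = assignments,
                 ratios = ratios, counties = counties,
                 manifest = manifest),
            class = "ten_americas_run")
}

#' @export
print.ten_americas_run <- function(x, ...) {
  cat("<ten_americas_run>", x$manifest$n_counties, "counties,",
      x$manifest$n_sims, "simulations, seed", x$manifest$seed, "\n")
  e0 <- x$life_expectancy |>
    filter(.data$quantity == "e0", .data$sex == "both",
           .data$year == max(.data$year))
  print(e0 |> select("america_id", "mean", "lower", "upper"))
  invisible(x)
}

#' Parameter-recovery study on synthetic data
#'
#' Repeatedly simulates vital statistics with known hazards and a known
#' misreporting matrix, runs the misclassification correction and
#' life-table pipeline, and asks two calibration questions: (i) are
#' corrected America-level life expectancies at birth less biased than
#' uncorrected ones for the group whose deaths are misreported, and
#' (ii) do the 95% uncertainty intervals cover the true values at close
#' to their nominal rate?  Truth is the life expectancy implied by the
#' expected mortality rates of the known hazards applied to the fixed
#' synthetic population.
#'
#' A single year of data is simulated per replicate (the population and
#' county set stay fixed); each replicate redraws deaths, misreporting
#' and ratio/Poisson simulations.
#'
#' @param n_replicates Number of scenario replicates (default 200).
#' @param n_sims Simulation draws per replicate (default 100).
#' @param config Generator configuration; the default uses one year,
#'   no census-base jump and no multirace category so the correction is
#'   the only moving part.
#' @param seed Root seed for the replicate streams.
#' @return List of class `recovery_study`: `results` (one row per
#'   replicate x America: truth, corrected and uncorrected estimates,
#'   interval, coverage flag) and `summary` (per-America coverage and
#'   mean absolute errors).
#' @export
parameter_recovery_study <- function(n_replicates = 200, n_sims = 100,
                                     config = sim_config(
                                       years = 2021L,
                                       discontinuity_scale = 0,
                                       multirace_share = 0),
                                     seed = 20L) {
  counties <- generate_counties(config)
  population <- generate_population(config, counties)
  assignments <- classify_americas(counties, config$races)
  validate_partition(assignments)
  density <- county_density_terciles(population, config$races)
  schema <- age_schema()

  mid <- age_midpoints(schema)[match(population$age_group,
                                     schema$age_group)]
  hazard <- gompertz_hazard(population$race, mid, config$gompertz_params,
                            male = population$sex == "male",
                            male_hazard_ratio = config$male_hazard_ratio)
  cells0 <- population |>
    mutate(hazard = hazard,
           rate = .data$value * hazard) |>
    left_join(counties |> select("county_id", "region"), by = "county_id") |>
    left_join(density, by = c("county_id", "race")) |>
    inner_join(assignments, by = c("county_id", "race"))
  cells0$age_sex <- age_sex_band(cells0$age_group, cells0$sex)
  races <- config$races
  n_races <- length(races)

  # both-sex output groups: america x age
  out_key <- tidyr::expand_grid(america_id = sort(unique(assignments$america_id)),
                                age_group = schema$age_group)
  cells0$out_i <- match(paste(cells0$america_id, cells0$age_group),
                        paste(out_key$america_id, out_key$age_group))
  stratum_key <- paste(cells0$county_id, cells0$age_group, cells0$sex)
  cells0$stratum_i <- match(stratum_key, sort(unique(stratum_key)))

  pop_agg <- rowsum(cells0$value, cells0$out_i)[, 1]
  m_true <- rowsum(cells0$rate, cells0$out_i)[, 1] / pop_agg
  americas <- sort(unique(out_key$america_id))
  n_amer <- length(americas)
  m_true_mat <- matrix(m_true, nrow = nrow(schema))
  truth <- life_table_engine(m_true_mat, schema)$e[1, ]

  # rows of each race block, sorted by stratum so blocks align across races
  race_rows <- lapply(races, function(r) {
    ix <- which(cells0$race == r)
    ix[order(stratum_key[ix])]
  })
  names(race_rows) <- races

  # age-group-major reshape: (america x age) rows -> 19-row schedules
  e0_matrix <- function(agg_mat) {
    m_big <- matrix(as.vector(agg_mat / pop_agg), nrow = nrow(schema))
    matrix(life_table_engine(m_big, schema)$e[1, ], nrow = n_amer)
  }

  one_replicate <- function(k) {
    set.seed(sim_seed(seed, k))
    d_true <- rpois(nrow(cells0), cells0$rate)
    # misreport by true race, vectorised over aligned race blocks
    d_rec <- numeric(nrow(cells0))
    for (r in races) {
      alloc <- allocate_multinomial(d_true[race_rows[[r]]],
                                    config$misreport_matrix[r, races])
      for (j in seq_len(n_races)) {
        tgt <- race_rows[[races[j]]]
        d_rec[tgt] <- d_rec[tgt] + alloc[, j]
      }
    }
    # derive ratios on all four dimensions
    rat <- derive_ratio_table(cells0, d_true, d_rec)
    draws <- ratio_draw_matrices(rat, n_sims, seed = sim_seed(seed, k) + 1L)
    cells <- tibble(
      deaths = d_rec,
      stratum_i = cells0$stratum_i,
      out_i = cells0$out_i,
      r_o = draw_row_index(cells0$race, "all", draws$overall),
      r_a = draw_row_index(cells0$race, cells0$age_sex, draws$age_sex),
      r_g = draw_row_index(cells0$race, cells0$region, draws$region),
      r_d = draw_row_index(cells0$race, cells0$density_level, draws$density)
    )
    agg <- correct_and_aggregate(cells, draws, n_sims,
                                 n_out = nrow(out_key))
    agg <- poisson_matrix(agg, seed = sim_seed(seed, k) + 2L)
    e0 <- e0_matrix(agg)
    # uncorrected point estimate: recorded rates as-is
    e0_unc <- e0_matrix(matrix(rowsum(d_rec, cells0$out_i)[, 1], ncol = 1))[, 1]
    tibble(
      replicate = k,
      america_id = americas,
      truth = truth,
      e0_corrected = rowMeans(e0),
      lower = apply(e0, 1, quantile, 0.025, type = 7, names = FALSE),
      upper = apply(e0, 1, quantile, 0.975, type = 7, names = FALSE),
      e0_uncorrected = e0_unc
    )
  }

  results <- bind_rows(lapply(seq_len(n_replicates), one_replicate)) |>
    mutate(covered = .data$truth >= .data$lower & .data$truth <= .data$upper)
  summary <- results |>
    group_by(.data$america_id) |>
    summarise(coverage = mean(.data$covered),
              mae_corrected = mean(abs(.data$e0_corrected - .data$truth)),
              mae_uncorrected = mean(abs(.data$e0_uncorrected - .data$truth)),
              .groups = "drop")
  structure(list(results = results, summary = summary,
                 overall_coverage = mean(results$covered),
                 n_replicates = n_replicates, n_sims = n_sims),
            class = "recovery_study")
}

# grouped ratio table (same columns as derive_misclassification_ratios)
# computed from parallel true/recorded count vectors over cells0
derive_ratio_table <- function(cells0, d_true, d_rec) {
  dims <- list(overall = rep("all", nrow(cells0)),
               age_sex = cells0$age_sex,
               region = cells0$region,
               density = cells0$density_level)
  bind_rows(lapply(names(dims), function(dim) {
    key <- paste(cells0$race, dims[[dim]], sep = "|")
    num <- rowsum(d_true, key)[, 1]
    den <- rowsum(d_rec, key)[, 1]
    keep <- den > 0
    parts <- strsplit(names(num)[keep], "|", fixed = TRUE)
    tibble(race = vapply(parts, `[`, "", 1),
           dimension = dim,
           level = vapply(parts, `[`, "", 2),
           mean = num[keep] / den[keep],
           se = (num[keep] / den[keep]) *
             sqrt(1 / pmax(num[keep], 1) + 1 / den[keep]))
  }))
}

#' @export
print.recovery_study <- function(x, ...) {
  cat("<recovery_study>", x$n_replicates, "replicates x", x$n_sims,
      "simulations\n")
  cat("overall 95% UI coverage:",
      round_half_up(100 * x$overall_coverage, 1), "%\n")
  print(x$summary)
  invisible(x)
}
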