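test_that("multirace bridging allocates proportionally and conserves totals", {
  comp <- tibble::tibble(
    year = 2021, county_id = "c001", age_group = "55-59", sex = "female",
    race = c("black", "latino", "white"), share = c(0.5, 0.3, 0.2)
  )
  d <- one_stratum_deaths(c(black = 10, latino = 5, white = 20,
                            multirace = 100), value_col = "value")
  out <- bridge_multirace_deaths(d, comp)
  expect_setequal(out$race, c("black", "latino", "white"))
  expect_equal(out$value[out$race == "black"], 10 + 50)
  expect_equal(out$value[out$race == "latino"], 5 + 30)
  expect_equal(out$value[out$race == "white"], 20 + 20)
  expect_equal(sum(out$value), sum(d$value))

  no_multi <- one_stratum_deaths(c(black = 10, white = 20),
                                 value_col = "value")
  expect_equal(bridge_multirace_deaths(no_multi, comp)$value, c(10, 20))

  orphan <- one_stratum_deaths(c(multirace = 10), year = 1999,
                               value_col = "value")
  expect_error(bridge_multirace_deaths(orphan, comp), "composition")
})

test_that("log-normal ratio draws match their target moments", {
  ratios <- tibble::tibble(race = "aian", dimension = "overall",
                           level = "all", mean = 1.2, se = 0.1)
  draws <- draw_ratios_lognormal(ratios, n_sims = 100000, seed = 2)
  expect_equal(mean(draws$draw), 1.2, tolerance = 0.002 / 1.2)
  expect_lt(abs(mean(draws$draw) - 1.2), 0.002)
  expect_lt(abs(sd(draws$draw) - 0.1), 0.002)
  expect_true(all(draws$draw > 0))

  degenerate <- draw_ratios_lognormal(
    tibble::tibble(race = "x", dimension = "overall", level = "all",
                   mean = 1.07, se = 0), n_sims = 50, seed = 3)
  expect_true(all(degenerate$draw == 1.07))

  unit <- draw_ratios_lognormal(
    tibble::tibble(race = "x", dimension = "overall", level = "all",
                   mean = 1, se = 0), n_sims = 10, seed = 3)
  expect_true(all(unit$draw == 1))

  expect_error(draw_ratios_lognormal(
    tibble::tibble(race = "x", dimension = "overall", level = "all",
                   mean = -1, se = 0.1), 10, 1), "positive")
})

test_that("dimension combination is a multiplicative deviation from the overall ratio", {
  mk_draws <- function(overall, age_sex, region, density) {
    tibble::tibble(
      race = "aian",
      dimension = c("overall", "age_sex", "region", "density"),
      level = c("all", "65+.female", "south", "high"),
      sim = 1L,
      draw = c(overall, age_sex, region, density)
    )
  }
  strata <- tibble::tibble(race = "aian", age_sex = "65+.female",
                           region = "south", density_level = "high")
  # all components at the overall ratio: combination collapses to it
  expect_equal(combine_ratio_dimensions(mk_draws(1.1, 1.1, 1.1, 1.1),
                                        strata)$ratio, 1.1)
  # one active dimension passes through
  expect_equal(combine_ratio_dimensions(mk_draws(1.0, 1.2, 1.0, 1.0),
                                        strata)$ratio, 1.2)
  # general case: overall x prod(component / overall)
  got <- combine_ratio_dimensions(mk_draws(1.1, 1.21, 1.0, 1.1),
                                  strata)$ratio
  expect_equal(got, 1.1 * (1.21 / 1.1) * (1.0 / 1.1) * (1.1 / 1.1),
               tolerance = 1e-12)

  bad_strata <- tibble::tibble(race = "aian", age_sex = "0-24.male",
                               region = "south", density_level = "high")
  expect_error(combine_ratio_dimensions(mk_draws(1, 1, 1, 1), bad_strata),
               "age_sex")
})

test_that("applying ratios then rescaling conserves stratum totals exactly", {
  raw <- one_stratum_deaths(c(aian = 10, white = 90), value_col = "value")
  ratios <- tibble::tibble(race = c("aian", "white"), sim = 1L,
                           ratio = c(1.2, 1.0))
  out <- apply_and_rescale(raw, ratios)
  expect_equal(out$value[out$race == "aian"], 12 * 100 / 102,
               tolerance = 1e-9)
  expect_equal(out$value[out$race == "aian"], 11.7647, tolerance = 1e-4)
  expect_equal(out$value[out$race == "white"], 88.2353, tolerance = 1e-4)
  expect_equal(sum(out$value), 100, tolerance = 1e-12)

  # identity ratios: fixed point
  ident <- tibble::tibble(race = c("aian", "white"), sim = 1L, ratio = 1)
  expect_equal(apply_and_rescale(raw, ident)$value, raw$value)

  # single-race stratum: any ratio cancels
  solo <- one_stratum_deaths(c(aian = 37), value_col = "value")
  solo_r <- tibble::tibble(race = "aian", sim = 1L, ratio = 3.7)
  expect_equal(apply_and_rescale(solo, solo_r)$value, 37)
})

test_that("conservation holds across many strata and simulations", {
  set.seed(14)
  strata <- tidyr::expand_grid(year = 2020:2021,
                               county_id = sprintf("c%03d", 1:10),
                               age_group = c("55-59", "60-64"),
                               sex = c("female", "male"))
  raw <- tidyr::expand_grid(strata, race = race_labels()) |>
    dplyr::mutate(value = rpois(dplyr::n(), 40))
  ratios <- tidyr::expand_grid(race = race_labels(), sim = 1:20) |>
    dplyr::mutate(ratio = exp(rnorm(dplyr::n(), 0, 0.1)))
  out <- apply_and_rescale(raw, ratios)
  tot <- out |>
    dplyr::group_by(year, county_id, age_group, sex, sim) |>
    dplyr::summarise(value = sum(value), .groups = "drop") |>
    dplyr::left_join(
      raw |>
        dplyr::group_by(year, county_id, age_group, sex) |>
        dplyr::summarise(raw_total = sum(value), .groups = "drop"),
      by = c("year", "county_id", "age_group", "sex"))
  expect_lt(max(abs(tot$value - tot$raw_total) / tot$raw_total), 1e-9)
})

test_that("the Poisson layer has the right moments and is seed-stable", {
  tab <- tibble::tibble(
    year = 2021, county_id = sprintf("c%06d", 1:100000),
    age_group = "55-59", sex = "female", race = "white",
    sim = 1L, value = 50
  )
  out <- poisson_perturb(tab, seed = 15)
  expect_gte(mean(out$value), 49.9)
  expect_lte(mean(out$value), 50.1)
  expect_gte(var(out$value), 49.3)
  expect_lte(var(out$value), 50.7)

  again <- poisson_perturb(tab, seed = 15)
  expect_identical(out$value, again$value)

  zero <- tibble::tibble(sim = 1L, value = 0)
  expect_equal(poisson_perturb(zero, seed = 1)$value, 0L)
  expect_error(poisson_perturb(tibble::tibble(sim = 1L, value = -1), 1),
               "non-negative")
})

test_that("the pipeline's matrix correction path agrees with the tidy operations", {
  # two strata x two races x four dimensions x 3 sims, fixed draws
  races <- c("aian", "white")
  draws_tbl <- tidyr::expand_grid(
    race = races,
    dimension = c("overall", "age_sex", "region", "density"),
    sim = 1:3
  ) |>
    dplyr::mutate(
      level = dplyr::case_when(
        dimension == "overall" ~ "all",
        dimension == "age_sex" ~ "55-59.female",
        dimension == "region" ~ "south",
        dimension == "density" ~ "all"
      ),
      draw = 1 + 0.1 * (seq_along(sim) %% 5)
    )
  raw <- dplyr::bind_rows(
    one_stratum_deaths(c(aian = 30, white = 70), value_col = "value"),
    one_stratum_deaths(c(aian = 10, white = 90), value_col = "value") |>
      dplyr::mutate(county_id = "c002")
  )
  strata <- tidyr::expand_grid(race = races) |>
    dplyr::mutate(age_sex = "55-59.female", region = "south",
                  density_level = "all")
  combined <- combine_ratio_dimensions(draws_tbl, strata)
  tidy_out <- apply_and_rescale(raw, combined) |>
    dplyr::arrange(county_id, race, sim)

  # matrix path on the same inputs
  draw_mats <- lapply(split(draws_tbl, draws_tbl$dimension), function(d) {
    m <- matrix(d$draw, nrow = 2, byrow = TRUE)
    rownames(m) <- paste(unique(d$race), unique(d$level), sep = "|")
    m
  })
  cells <- tibble::tibble(
    deaths = c(30, 70, 10, 90),
    stratum_i = c(1L, 1L, 2L, 2L),
    out_i = c(1L, 2L, 1L, 2L),
    r_o = c(1L, 2L, 1L, 2L), r_a = c(1L, 2L, 1L, 2L),
    r_g = c(1L, 2L, 1L, 2L), r_d = c(1L, 2L, 1L, 2L)
  )
  agg <- tenamericas:::correct_and_aggregate(cells, draw_mats, 3, 2)
  tidy_agg <- tidy_out |>
    dplyr::group_by(race, sim) |>
    dplyr::summarise(value = sum(value), .groups = "drop")
  for (s in 1:3) {
    expect_equal(agg[1, s],
                 tidy_agg$value[tidy_agg$race == "aian" &
                                  tidy_agg$sim == s],
                 tolerance = 1e-12)
    expect_equal(agg[2, s],
                 tidy_agg$value[tidy_agg$race == "white" &
                                  tidy_agg$sim == s],
                 tolerance = 1e-12)
  }
})
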