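test_that("config validation rejects broken misreporting matrices and hazards", {
  bad <- default_misreport_matrix()
  bad[1, 1] <- bad[1, 1] + 1e-6
  expect_error(sim_config(misreport_matrix = bad), "sum to 1")
  bad2 <- default_misreport_matrix()
  bad2[1, 1] <- -bad2[1, 1]
  expect_error(sim_config(misreport_matrix = bad2), "non-negative")
  gp <- default_gompertz_params()
  gp$makeham[1] <- -1
  expect_error(sim_config(gompertz_params = gp), "positive")
  expect_error(sim_config(n_counties = 5), "at least 10")
})

test_that("county attributes stay in their domains and populate all ten Americas", {
  cfg <- sim_config(seed = 1)
  cty <- generate_counties(cfg)
  expect_equal(nrow(cty), 200)
  expect_true(all(cty$rucc %in% 1:9))
  expect_true(all(cty$state %in% tenamericas:::state_codes))
  expect_true(all(cty$dissimilarity_index >= 0 &
                    cty$dissimilarity_index <= 100))
  expect_true(all(cty$nhpi_share >= 0 & cty$nhpi_share <= 1))
  expect_true(all(cty$income_white > 0 & cty$income_black > 0))
  counts <- validate_partition(classify_americas(cty))
  expect_true(all(counts$n_units > 0))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_counties = 200, years = 2020:2021, seed = 4)
  a <- generate_counties(cfg)
  b <- generate_counties(cfg)
  expect_identical(a, b)
  pa <- generate_population(cfg, a)
  pb <- generate_population(cfg, b)
  expect_identical(pa, pb)
  da <- simulate_deaths(pa, cfg$gompertz_params, seed = 99)
  db <- simulate_deaths(pb, cfg$gompertz_params, seed = 99)
  expect_identical(da, db)
})

test_that("the low-income county fraction tracks its configured rate", {
  cfg <- sim_config(n_counties = 10000, low_income_fraction = 0.5,
                    seed = 42)
  cty <- generate_counties(cfg)
  frac <- mean(cty$income_white < 32363)
  expect_gte(frac, 0.49)
  expect_lte(frac, 0.51)
})

test_that("population cells are positive and the census-base jump has the configured size", {
  cty_cfg <- sim_config(n_counties = 200, years = 2016:2021,
                        discontinuity_scale = 0, multirace_share = 0,
                        seed = 6)
  cty <- generate_counties(cty_cfg)
  pop0 <- generate_population(cty_cfg, cty)
  expect_true(all(pop0$value > 0))

  jumps <- function(pop, dyear) {
    series <- dplyr::summarise(
      dplyr::group_by(pop, .data$year, .data$county_id, .data$race),
      value = sum(.data$value), .groups = "drop")
    wide <- tidyr::pivot_wider(series, names_from = "year",
                               values_from = "value")
    v2 <- wide[[as.character(dyear)]]
    v1 <- wide[[as.character(dyear - 1)]]
    v0 <- wide[[as.character(dyear - 2)]]
    v2 / (v1 * (v1 / v0)) - 1   # jump relative to the local growth trend
  }
  expect_lt(max(abs(jumps(pop0, 2020))), 1e-9)

  cfg5 <- sim_config(n_counties = 200, years = 2016:2021,
                     discontinuity_scale = 0.05, multirace_share = 0,
                     seed = 6)
  pop5 <- generate_population(cfg5, generate_counties(cfg5))
  mean_jump <- mean(abs(jumps(pop5, 2020)))
  expect_gte(mean_jump, 0.04)
  expect_lte(mean_jump, 0.06)
})

test_that("a multirace category appears only from the base-change year on", {
  cfg <- sim_config(n_counties = 200, years = 2018:2021, seed = 7)
  pop <- generate_population(cfg, generate_counties(cfg))
  by_year <- dplyr::count(pop[pop$race == "multirace", ], year)
  expect_setequal(by_year$year, 2020:2021)
})

test_that("simulated deaths have Poisson moments and respect empty strata", {
  # constant hazard via a pure Makeham term
  params <- tibble::tibble(race = "white", level = 0, slope = 0,
                           makeham = 0.02)
  pop <- tibble::tibble(
    year = 2021, county_id = sprintf("c%04d", 1:1000),
    age_group = "55-59", sex = "female", race = "white", value = 1e6
  )
  d <- simulate_deaths(pop, params, seed = 8, male_hazard_ratio = 1)
  expect_equal(mean(d$deaths), 20000, tolerance = 300 / 20000)
  expect_gte(mean(d$deaths), 19700)
  expect_lte(mean(d$deaths), 20300)

  pop0 <- pop[1, ]
  pop0$value <- 0
  expect_equal(simulate_deaths(pop0, params, seed = 8)$deaths, 0L)

  d2 <- simulate_deaths(pop, params, seed = 8, male_hazard_ratio = 1)
  expect_identical(d$deaths, d2$deaths)

  popbig <- pop[1, ]
  popbig$value <- 1e15
  expect_error(simulate_deaths(popbig, params, seed = 8), "overflow")
})

test_that("misreporting permutes race labels but conserves stratum totals", {
  races <- race_labels()
  ident <- diag(5)
  dimnames(ident) <- list(races, races)
  d <- one_stratum_deaths(c(aian = 100L, asian_nhpi = 50L, black = 200L,
                            latino = 150L, white = 500L))
  b <- apply_misreporting(d, ident, seed = 1)
  expect_identical(b$deaths_recorded, b$deaths_true)

  flow <- ident
  flow["aian", "aian"] <- 0.8
  flow["aian", "white"] <- 0.2
  d2 <- one_stratum_deaths(c(aian = 10000L, white = 0L))
  b2 <- apply_misreporting(d2, flow, seed = 2)
  rec_aian <- b2$deaths_recorded[b2$race == "aian"]
  expect_gte(rec_aian, 7840)
  expect_lte(rec_aian, 8160)
  expect_equal(sum(b2$deaths_recorded), sum(b2$deaths_true))

  # conservation under an arbitrary matrix, stratum by stratum
  cfg <- sim_config(n_counties = 200, years = 2021L, seed = 5)
  pop <- generate_population(cfg, generate_counties(cfg))
  dd <- simulate_deaths(pop, cfg$gompertz_params, seed = 5)
  bb <- apply_misreporting(dd, cfg$misreport_matrix, seed = 6)
  per_stratum <- dplyr::summarise(
    dplyr::group_by(bb, .data$year, .data$county_id, .data$age_group,
                    .data$sex),
    ok = sum(.data$deaths_true) == sum(.data$deaths_recorded),
    .groups = "drop")
  expect_true(all(per_stratum$ok))

  bad <- ident
  bad[1, 1] <- 0.5
  expect_error(apply_misreporting(d, bad, seed = 1), "row-stochastic")
})

test_that("derived ratios recover the closed-form flow balance", {
  races <- race_labels()
  flow <- diag(5)
  dimnames(flow) <- list(races, races)
  flow["aian", "aian"] <- 0.8
  flow["aian", "white"] <- 0.2
  # 1e6 AIAN deaths, tiny White pool so the AIAN ratio converges to 1/0.8
  d <- one_stratum_deaths(c(aian = 1000000L, white = 1000L))
  b <- apply_misreporting(d, flow, seed = 3)
  cty <- make_attrs(1)
  cty$region <- "midwest"
  r <- derive_misclassification_ratios(b, cty, density = NULL,
                                       dimensions = "overall")
  aian_ratio <- r$mean[r$race == "aian"]
  expect_equal(aian_ratio, 1.25, tolerance = 0.01)
  expect_true(all(r$se > 0))

  ident <- diag(5)
  dimnames(ident) <- list(races, races)
  d5 <- one_stratum_deaths(c(aian = 100L, asian_nhpi = 50L, black = 200L,
                             latino = 150L, white = 500L))
  b5 <- apply_misreporting(d5, ident, seed = 4)
  r5 <- derive_misclassification_ratios(b5, cty, density = NULL,
                                        dimensions = "overall")
  expect_true(all(r5$mean == 1))

  # a race with no recorded deaths anywhere in a cell is dropped, loudly
  d0 <- one_stratum_deaths(c(aian = 0L, white = 100L))
  b0 <- apply_misreporting(d0, ident, seed = 5)
  expect_warning(
    r0 <- derive_misclassification_ratios(b0, cty, density = NULL,
                                          dimensions = "overall"),
    "zero recorded")
  expect_false("aian" %in% r0$race)
})

test_that("synthetic inputs round-trip through the CSV writer", {
  cfg <- sim_config(n_counties = 200, years = 2021L, seed = 9)
  cty <- generate_counties(cfg)
  pop <- generate_population(cfg, cty)
  d <- simulate_deaths(pop, cfg$gompertz_params, seed = 9)
  b <- apply_misreporting(d, cfg$misreport_matrix, seed = 10)
  r <- derive_misclassification_ratios(b, cty,
                                       county_density_terciles(pop))
  dir <- withr::local_tempdir()
  write_synthetic_vitals(dir, cfg, cty, pop, b, r)
  expect_setequal(list.files(dir),
                  c("county_attributes.csv", "population.csv",
                    "deaths.csv", "misclassification_ratios.csv",
                    "config.yaml"))
  back <- readr::read_csv(file.path(dir, "misclassification_ratios.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(r))
})
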