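test_that("dissimilarity index hits its analytic anchor points", {
  expect_equal(dissimilarity_index(c(10, 10), c(50, 50)), 0)
  expect_equal(dissimilarity_index(c(100, 0), c(0, 250)), 100)
  expect_equal(dissimilarity_index(c(10, 30), c(90, 10)), 65)
  expect_error(dissimilarity_index(c(0, 0), c(1, 2)), "zero")
  expect_error(dissimilarity_index(c(-1, 2), c(1, 2)), "non-negative")
  expect_error(dissimilarity_index(numeric(0), numeric(0)), "non-empty")
})

test_that("metropolitan and income predicates apply the definitional thresholds", {
  expect_true(is_high_population_metropolitan(make_attrs(rucc = 1L)))
  expect_false(is_high_population_metropolitan(make_attrs(rucc = 3L)))
  expect_false(is_high_population_metropolitan(make_attrs(rucc = 9L)))
  expect_true(is_nonmetropolitan(make_attrs(rucc = 4L)))
  expect_true(is_nonmetropolitan(make_attrs(rucc = 9L)))
  expect_false(is_nonmetropolitan(make_attrs(rucc = 1L)))
  expect_false(is_nonmetropolitan(make_attrs(rucc = 3L)))
  # strictly below the $32,363 median
  expect_true(is_low_income(make_attrs(income_white = 25000), "white"))
  expect_false(is_low_income(make_attrs(income_white = 32363), "white"))
  expect_true(is_low_income(make_attrs(income_white = 32362.99), "white"))
  expect_error(is_low_income(make_attrs(), "unknown_race"), "income")
})

test_that("assignment rules reproduce the definitional examples", {
  cases <- list(
    list(race = "black",
         attrs = make_attrs(rucc = 1L, dissimilarity_index = 72),
         want = 7L),
    list(race = "black",
         attrs = make_attrs(rucc = 1L, dissimilarity_index = 50),
         want = 6L),
    list(race = "black",
         attrs = make_attrs(rucc = 6L, deep_south = TRUE,
                            income_black = 20000, state = "MS"),
         want = 9L),
    list(race = "black",
         attrs = make_attrs(rucc = 6L, deep_south = TRUE,
                            income_black = 50000, state = "MS"),
         want = 6L),
    list(race = "latino", attrs = make_attrs(state = "TX"), want = 5L),
    list(race = "latino", attrs = make_attrs(state = "NY"), want = 2L),
    list(race = "white",
         attrs = make_attrs(rucc = 6L, appalachia = TRUE,
                            income_white = 28000),
         want = 8L),
    list(race = "white",
         attrs = make_attrs(rucc = 1L, income_white = 60000),
         want = 3L),
    list(race = "white",
         attrs = make_attrs(state = "ND", rucc = 7L, income_white = 28000),
         want = 4L),
    list(race = "aian", attrs = make_attrs(state = "NM"), want = 10L),
    list(race = "aian", attrs = make_attrs(state = "CA"), want = 3L),
    list(race = "asian_nhpi", attrs = make_attrs(nhpi_share = 0.1),
         want = 1L),
    list(race = "asian_nhpi", attrs = make_attrs(nhpi_share = 0.5),
         want = 3L)
  )
  for (cs in cases) {
    expect_identical(assign_america(cs$attrs, cs$race), cs$want,
                     info = paste(cs$race, "->", cs$want))
  }
  expect_error(assign_america(make_attrs(), "martian"))
})

test_that("highly segregated metro precedence beats the non-metro South rule", {
  # a (hypothetical) unit meeting every America-7 and America-9 criterion
  # except the mutually exclusive RUCC maps by the metro rule first
  attrs <- make_attrs(rucc = 1L, dissimilarity_index = 80,
                      deep_south = TRUE, income_black = 15000, state = "MS")
  expect_identical(assign_america(attrs, "black"), 7L)
})

test_that("classification partitions every county-race unit exactly once", {
  for (seed in c(11, 12, 13)) {
    attrs <- random_attrs(300, seed)
    asg <- classify_americas(attrs)
    expect_equal(nrow(asg), 300 * 5)
    expect_equal(anyDuplicated(paste(asg$county_id, asg$race)), 0L)
    counts <- validate_partition(asg, require_all_americas = FALSE)
    expect_equal(sum(counts$n_units), 300 * 5)
    expect_true(all(asg$america_id %in% 1:10))
  }
})

test_that("raising White income across the threshold only moves units toward America 3", {
  attrs <- random_attrs(200, 21)
  low <- classify_americas(attrs, races = "white")
  attrs_hi <- attrs
  attrs_hi$income_white <- 50000
  high <- classify_americas(attrs_hi, races = "white")
  # any unit in 3 under low income stays in 3; units in {4, 8} may only
  # move to 3
  expect_true(all(high$america_id[low$america_id == 3L] == 3L))
  expect_true(all(high$america_id[low$america_id %in% c(4L, 8L)] == 3L |
                    high$america_id[low$america_id %in% c(4L, 8L)] ==
                      low$america_id[low$america_id %in% c(4L, 8L)]))
  expect_false(any(low$america_id == 3L & high$america_id %in% c(4L, 8L)))
})

test_that("partition validation names missing, duplicated and empty groups", {
  attrs <- random_attrs(300, 31)
  asg <- classify_americas(attrs)
  units <- asg[c("county_id", "race")]
  expect_silent(validate_partition(asg, units,
                                   require_all_americas = FALSE))
  expect_error(validate_partition(asg[-1, ], units, FALSE), "missing")
  expect_error(validate_partition(rbind(asg, asg[1, ]), units, FALSE),
               "more than once")
  only_white <- classify_americas(make_attrs(5), races = "white")
  expect_error(validate_partition(only_white), "empty Americas")
})
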