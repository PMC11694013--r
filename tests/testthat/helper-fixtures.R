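# small in-code fixtures shared across test files

# a fully specified county attribute row, overridable per test
make_attrs <- function(n = 1, ...) {
  base <- tibble::tibble(
    county_id = sprintf("c%03d", seq_len(n)),
    state = "OH", rucc = 5L, dissimilarity_index = 30,
    nhpi_share = 0.1, appalachia = FALSE,
    lower_mississippi_valley = FALSE, deep_south = FALSE,
    income_aian = 40000, income_asian_nhpi = 40000,
    income_black = 40000, income_latino = 40000, income_white = 40000
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# randomised but valid attribute tables for property-style tests
random_attrs <- function(n, seed) {
  set.seed(seed)
  make_attrs(
    n,
    state = sample(c("TX", "OH", "MN", "MS", "AZ", "WV", "GA", "NY"),
                   n, replace = TRUE),
    rucc = sample(1:9, n, replace = TRUE),
    dissimilarity_index = runif(n, 0, 100),
    nhpi_share = runif(n),
    appalachia = runif(n) < 0.3,
    lower_mississippi_valley = runif(n) < 0.2,
    deep_south = runif(n) < 0.2,
    income_black = runif(n, 15000, 60000),
    income_white = runif(n, 15000, 60000)
  )
}

# one-stratum death table over races, as a tidy tibble
one_stratum_deaths <- function(counts, year = 2021, value_col = "deaths") {
  out <- tibble::tibble(
    year = year, county_id = "c001", age_group = "55-59", sex = "female",
    race = names(counts), value = unname(counts)
  )
  names(out)[names(out) == "value"] <- value_col
  out
}
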