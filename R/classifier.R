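#' Black-White dissimilarity index
#'
#' Index of dissimilarity over subunits (e.g. census tracts) of a county:
#' \deqn{D = 50 \sum_i | b_i / B - w_i / W |}
#' where \eqn{b_i, w_i} are subunit counts and \eqn{B, W} the group
#' totals.  0 means the two groups are identically distributed across
#' subunits; 100 means complete segregation.
#'
#' @param black Non-negative counts of the Black population by subunit.
#' @param white Non-negative counts of the White population by subunit,
#'   same length.
#' @return The index, a scalar in \[0, 100\].
#' @examples
#' dissimilarity_index(c(10, 30), c(90, 10))  # 65
#' @export
dissimilarity_index <- function(black, white) {
  if (length(black) != length(white) || length(black) == 0L) {
    abort("black and white must be non-empty vectors of equal length")
  }
  if (any(black < 0) || any(white < 0)) abort("counts must be non-negative")
  B <- sum(black); W <- sum(white)
  if (B == 0 || W == 0) {
    abort("dissimilarity index undefined: a group total is zero")
  }
  50 * sum(abs(black / B - white / W))
}

# threshold: median all-race county income per capita, 2020 USD
income_threshold <- 32363

# state groups used by the definitions
southwest_states <- c("AZ", "CO", "NM", "TX")
west_states <- c("AZ", "CO", "ID", "KS", "MN", "MT", "NE", "NV", "NM",
                 "ND", "OK", "SD", "UT", "WY")
northlands_states <- c("IA", "MN", "MT", "NE", "ND", "SD")
deep_south_states <- c("SC", "GA", "AL", "MS", "LA")

#' County classification predicates
#'
#' Helpers applying the definitional thresholds: a county is
#' high-population metropolitan iff its Rural-Urban Continuum Code (RUCC)
#' is 1 (metro area of one million or more); non-metropolitan iff RUCC is
#' 4-9; low-income for a race iff that race's county income per capita is
#' strictly below $32,363 (the median all-race county income per capita
#' in 2020).
#'
#' @param attrs A data frame of county attributes with columns `rucc` and
#'   `income_<race>` (one per race label).
#' @param race Race label, e.g. `"white"` or `"black"`.
#' @return Logical vector, one element per county row.
#' @export
is_high_population_metropolitan <- function(attrs) {
  attrs$rucc == 1L
}

#' @rdname is_high_population_metropolitan
#' @export
is_nonmetropolitan <- function(attrs) {
  attrs$rucc >= 4L & attrs$rucc <= 9L
}

#' @rdname is_high_population_metropolitan
#' @export
is_low_income <- function(attrs, race) {
  col <- paste0("income_", race)
  if (!col %in% names(attrs)) {
    abort(paste0("no income column for race '", race, "' (expected ", col, ")"))
  }
  inc <- attrs[[col]]
  if (anyNA(inc)) abort(paste0("missing income for race '", race, "'"))
  inc < income_threshold
}

#' Race labels used throughout the package
#'
#' Asian and NHPI (Native Hawaiian or Pacific Islander) are carried as a
#' single combined label because the two cannot be fully distinguished in
#' death records for the early study years.
#' @return Character vector of the five race/ethnicity labels.
#' @export
race_labels <- function() c("aian", "asian_nhpi", "black", "latino", "white")

#' Assign county-by-race units to the ten Americas
#'
#' Applies the definitional rules to every combination of county and
#' race/ethnicity label, producing a mutually exclusive and collectively
#' exhaustive partition:
#'
#' * America 1 - Asian/NHPI in counties where NHPI are < 30% of the
#'   combined Asian+NHPI population; America 3 otherwise.
#' * America 5 - Latino in the Southwest (AZ, CO, NM, TX); America 2
#'   elsewhere.
#' * America 10 - AIAN in the West (14 interior states); America 3
#'   otherwise.
#' * America 7 - Black in highly segregated (dissimilarity >= 60),
#'   high-population metropolitan counties; America 9 - Black in
#'   non-metropolitan, low-income counties of the Lower Mississippi
#'   Valley or Deep South; America 6 otherwise.
#' * America 4 - White in non-metropolitan, low-income Northlands
#'   counties; America 8 - White in low-income Appalachia or Lower
#'   Mississippi Valley counties; America 3 otherwise.
#'
#' America 7 takes precedence over America 9 and America 4 over
#' America 8 should a unit ever satisfy both (unreachable with valid
#' RUCC codes for 7 vs 9; the fixed order keeps the map deterministic).
#'
#' @param attrs County attribute table: `county_id`, `state`, `rucc`,
#'   `dissimilarity_index`, `nhpi_share`, logical flags `appalachia`,
#'   `lower_mississippi_valley`, `deep_south`, and `income_<race>`
#'   columns.
#' @param races Race labels to classify; default all five.
#' @return A tibble `county_id`, `race`, `america_id` with one row per
#'   county-race unit.
#' @examples
#' attrs <- tibble::tibble(
#'   county_id = "c1", state = "TX", rucc = 1L, dissimilarity_index = 40,
#'   nhpi_share = 0.1, appalachia = FALSE, lower_mississippi_valley = FALSE,
#'   deep_south = FALSE, income_aian = 4e4, income_asian_nhpi = 4e4,
#'   income_black = 4e4, income_latino = 4e4, income_white = 4e4)
#' classify_americas(attrs)
#' @export
classify_americas <- function(attrs, races = race_labels()) {
  unknown <- setdiff(races, race_labels())
  if (length(unknown) > 0L) {
    abort(paste0("unknown race label(s): ", paste(unknown, collapse = ", ")))
  }
  purrr::map_dfr(races, function(r) {
    tibble(county_id = attrs$county_id, race = r,
           america_id = assign_america(attrs, r))
  }) |>
    arrange(.data$county_id, .data$race)
}

#' @rdname classify_americas
#' @param race A single race label; `assign_america` is the vectorised
#'   single-race rule behind [classify_americas()].
#' @export
assign_america <- function(attrs, race) {
  race <- match.arg(race, race_labels())
  n <- nrow(attrs)
  switch(race,
    latino = ifelse(attrs$state %in% southwest_states, 5L, 2L),
    asian_nhpi = ifelse(attrs$nhpi_share < 0.30, 1L, 3L),
    aian = ifelse(attrs$state %in% west_states, 10L, 3L),
    black = {
      a7 <- is_high_population_metropolitan(attrs) &
        attrs$dissimilarity_index >= 60
      a9 <- is_nonmetropolitan(attrs) &
        (attrs$lower_mississippi_valley | attrs$deep_south) &
        is_low_income(attrs, "black")
      ifelse(a7, 7L, ifelse(a9, 9L, 6L))
    },
    white = {
      a4 <- is_nonmetropolitan(attrs) &
        attrs$state %in% northlands_states &
        is_low_income(attrs, "white")
      a8 <- (attrs$appalachia | attrs$lower_mississippi_valley) &
        is_low_income(attrs, "white")
      ifelse(a4, 4L, ifelse(a8, 8L, 3L))
    }
  )
}

#' Validate an America assignment as a partition
#'
#' Checks that the assignment is a bijection onto the expected unit set:
#' every county-race unit appears exactly once, no unknown units appear,
#' and (optionally) every one of the ten Americas is non-empty.
#'
#' @param assignments Output of [classify_americas()].
#' @param units A data frame of expected units (`county_id`, `race`);
#'   defaults to the units present in `assignments`.
#' @param require_all_americas If `TRUE` (default), fail when any of the
#'   ten Americas has no unit.
#' @return Invisibly, a tibble of per-America unit counts; errors on any
#'   violation, naming the offending units or empty Americas.
#' @export
validate_partition <- function(assignments, units = NULL,
                               require_all_americas = TRUE) {
  key <- paste(assignments$county_id, assignments$race, sep = "/")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    abort(paste0("units assigned more than once: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.null(units)) {
    ukey <- paste(units$county_id, units$race, sep = "/")
    miss <- setdiff(ukey, key)
    extra <- setdiff(key, ukey)
    if (length(miss) > 0L) {
      abort(paste0("units missing from the assignment: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
    if (length(extra) > 0L) {
      abort(paste0("assignment contains unknown units: ",
                   paste(head(extra, 5), collapse = ", ")))
    }
  }
  counts <- assignments |>
    count(.data$america_id, name = "n_units") |>
    right_join(tibble(america_id = 1:10), by = "america_id") |>
    mutate(n_units = dplyr::coalesce(.data$n_units, 0L)) |>
    arrange(.data$america_id)
  if (require_all_americas && any(counts$n_units == 0L)) {
    abort(paste0("empty Americas: ",
                 paste(counts$america_id[counts$n_units == 0L],
                       collapse = ", ")))
  }
  invisible(counts)
}
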