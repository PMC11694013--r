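state_codes <- c(
  "AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "FL", "GA",
  "HI", "ID", "IL", "IN", "IA", "KS", "KY", "LA", "ME", "MD",
  "MA", "MI", "MN", "MS", "MO", "MT", "NE", "NV", "NH", "NJ",
  "NM", "NY", "NC", "ND", "OH", "OK", "OR", "PA", "RI", "SC",
  "SD", "TN", "TX", "UT", "VT", "VA", "WA", "WV", "WI", "WY"
)

census_region_map <- c(
  CT = "northeast", ME = "northeast", MA = "northeast", NH = "northeast",
  RI = "northeast", VT = "northeast", NJ = "northeast", NY = "northeast",
  PA = "northeast",
  IL = "midwest", IN = "midwest", MI = "midwest", OH = "midwest",
  WI = "midwest", IA = "midwest", KS = "midwest", MN = "midwest",
  MO = "midwest", NE = "midwest", ND = "midwest", SD = "midwest",
  DE = "south", FL = "south", GA = "south", MD = "south", NC = "south",
  SC = "south", VA = "south", WV = "south", AL = "south", KY = "south",
  MS = "south", TN = "south", AR = "south", LA = "south", OK = "south",
  TX = "south",
  AZ = "west", CO = "west", ID = "west", MT = "west", NV = "west",
  NM = "west", UT = "west", WY = "west", AK = "west", CA = "west",
  HI = "west", OR = "west", WA = "west"
)

# per-state probabilities of carrying a regional flag; regional county
# lists are external resources, so membership is sampled instead
appalachia_probs <- c(
  WV = 0.9, KY = 0.6, TN = 0.5, PA = 0.5, VA = 0.4, OH = 0.35,
  NC = 0.35, AL = 0.35, GA = 0.3, MD = 0.25, SC = 0.25, NY = 0.2,
  MS = 0.2
)
lmv_probs <- c(
  LA = 0.6, MS = 0.6, AR = 0.5, TN = 0.3, MO = 0.25, KY = 0.2,
  IL = 0.15
)

#' Default Gompertz-Makeham hazard parameters by race/ethnicity
#'
#' The synthetic hazard is \eqn{h(x) = c + a e^{b x}} (Makeham constant
#' `makeham`, Gompertz `level` and `slope`).  The defaults produce
#' life expectancies in the low 70s to mid 80s with the ordering seen in
#' national race-stratified statistics (Asian highest, AIAN lowest), so
#' the synthetic populations span a realistic disparity range.
#'
#' @return Tibble with columns `race`, `level`, `slope`, `makeham`.
#' @export
default_gompertz_params <- function() {
  tibble(
    race    = c("aian", "asian_nhpi", "black", "latino", "white", "multirace"),
    level   = c(7e-5, 1.8e-5, 6e-5, 3e-5, 4e-5, 4e-5),
    slope   = c(0.088, 0.092, 0.09, 0.09, 0.09, 0.09),
    makeham = c(5e-4, 1e-4, 3e-4, 1.5e-4, 2e-4, 2e-4)
  )
}

#' Default race-misreporting matrix
#'
#' Row-stochastic matrix over the five race labels: entry (r, s) is the
#' probability a death whose decedent self-identified as race r is
#' recorded as race s on the certificate.  The defaults concentrate
#' misreporting in AIAN-to-White flows (the dominant direction in linkage
#' studies, implying self-report/recorded ratios well above 1 for AIAN),
#' with small Latino and Asian/NHPI flows and near-perfect recording for
#' Black and White decedents.
#'
#' @return A 5x5 matrix with dimnames `race_labels()`.
#' @export
default_misreport_matrix <- function() {
  r <- race_labels()
  m <- matrix(c(
    # aian  asian  black  latino white     (recorded)
    0.78,  0.00,  0.01,  0.02,  0.19,   # aian (true)
    0.00,  0.97,  0.00,  0.01,  0.02,   # asian_nhpi
    0.00,  0.00,  0.99,  0.00,  0.01,   # black
    0.00,  0.00,  0.01,  0.96,  0.03,   # latino
    0.001, 0.00,  0.002, 0.002, 0.995   # white
  ), nrow = 5, byrow = TRUE, dimnames = list(r, r))
  m
}

#' Configuration for the synthetic vital-statistics generator
#'
#' Bundles every generator parameter with validation.  The defaults
#' describe the study conditions the package is exercised under: 200
#' counties, seven recent years spanning the 2020 census-base change,
#' the five race/ethnicity labels, Gompertz-Makeham hazards spanning a
#' realistic life-expectancy range, and an AIAN-dominated misreporting
#' process.
#'
#' @param n_counties Number of synthetic counties (at least 10).
#' @param years Inclusive vector of calendar years.
#' @param races Race/ethnicity labels (see [race_labels()]).
#' @param gompertz_params Hazard parameters, see
#'   [default_gompertz_params()].
#' @param misreport_matrix Row-stochastic misreporting matrix, see
#'   [default_misreport_matrix()].
#' @param male_hazard_ratio Multiplier on the hazard for males.
#' @param discontinuity_year First year on the new census base; the
#'   population series jumps here and a "Two or More Races" category
#'   appears from this year on.
#' @param discontinuity_scale Mean absolute relative size of the
#'   census-base jump (0 disables it).
#' @param multirace_share Share of each cell's population reported as
#'   Two or More Races from `discontinuity_year` on.
#' @param low_income_fraction Fraction of counties whose race-specific
#'   income per capita falls below the $32,363 low-income threshold.
#' @param income_sdlog Log-scale spread of county incomes.
#' @param tracts_per_county Subunits used to compute the Black-White
#'   dissimilarity index.
#' @param seed Integer seed governing all generator randomness.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_counties = 50, years = 2019:2021, seed = 7)
#' @export
sim_config <- function(n_counties = 200,
                       years = 2015:2021,
                       races = race_labels(),
                       gompertz_params = default_gompertz_params(),
                       misreport_matrix = default_misreport_matrix(),
                       male_hazard_ratio = 1.4,
                       discontinuity_year = 2020,
                       discontinuity_scale = 0.03,
                       multirace_share = 0.03,
                       low_income_fraction = 0.5,
                       income_sdlog = 0.35,
                       tracts_per_county = 12,
                       seed = 1L) {
  if (n_counties < 10) abort("n_counties must be at least 10")
  if (!all(races %in% race_labels())) abort("unknown race labels in config")
  mm <- misreport_matrix[races, races, drop = FALSE]
  if (any(mm < 0)) abort("misreport_matrix entries must be non-negative")
  if (any(abs(rowSums(mm) - 1) > 1e-12)) {
    abort("every misreport_matrix row must sum to 1 (tolerance 1e-12)")
  }
  gp <- gompertz_params
  ages <- age_midpoints()
  for (i in seq_len(nrow(gp))) {
    h <- gp$makeham[i] + gp$level[i] * exp(gp$slope[i] * ages)
    if (any(h <= 0)) {
      abort(paste0("hazard not strictly positive for race ", gp$race[i]))
    }
  }
  structure(list(
    n_counties = as.integer(n_counties), years = as.integer(years),
    races = races, gompertz_params = gp, misreport_matrix = mm,
    male_hazard_ratio = male_hazard_ratio,
    discontinuity_year = as.integer(discontinuity_year),
    discontinuity_scale = discontinuity_scale,
    multirace_share = multirace_share,
    low_income_fraction = low_income_fraction,
    income_sdlog = income_sdlog,
    tracts_per_county = as.integer(tracts_per_county),
    seed = as.integer(seed),
    # the delta-method SE attached to derived ratios is a stand-in for
    # the linkage-study SEs used with real data
    ratio_se_method = "delta_poisson"
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  counties:", x$n_counties, " years:", min(x$years), "-",
      max(x$years), " seed:", x$seed, "\n")
  cat("  races:", paste(x$races, collapse = ", "), "\n")
  cat("  census-base jump:", x$discontinuity_scale, "at",
      x$discontinuity_year, "\n")
  invisible(x)
}
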