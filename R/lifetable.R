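#' Convert an age-specific death rate to a probability of dying
#'
#' Standard abridged life-table conversion
#' \eqn{q = n m / (1 + (n - a) m)}, capped at 1.  For an open (infinite
#' width) interval the probability is 1 by convention.
#'
#' @param m Death rate (deaths per person-year), non-negative.
#' @param n Interval width in years (may be `Inf` for the terminal group).
#' @param a Average years lived in the interval by those dying in it.
#' @return Probability of death in the interval, in \[0, 1\].
#' @examples
#' mx_to_qx(0.02, 5, 2.5)
#' @export
mx_to_qx <- function(m, n, a) {
  if (any(m < 0, na.rm = TRUE)) abort("death rates must be non-negative")
  q <- ifelse(is.finite(n), n * m / (1 + (n - a) * m), 1)
  pmin(q, 1)
}

#' Average years lived by those dying in each interval
#'
#' The infant interval uses the Coale-Demeny-style rule
#' \eqn{a(0) = 0.07 + 1.7 m(0)} (capped at the interval width); other
#' closed intervals use the midpoint \eqn{n/2}; the terminal interval has
#' no `a` (its person-years come from the terminal strategy).
#'
#' @param m Vector of death rates in schema order.
#' @param schema Age schema, see [age_schema()].
#' @return Numeric vector of `a` values (`NA` for the terminal group).
#' @export
default_nax <- function(m, schema = age_schema()) {
  n <- schema$age_width
  a <- n / 2
  a[1] <- pmin(0.07 + 1.7 * m[1], n[1])
  a[!is.finite(n)] <- NA_real_
  a
}

#' Remaining life expectancy in the terminal age group
#'
#' Estimates e(85+) (or any open interval) from the terminal death rate.
#' `constant_hazard` returns the stationary value `1/m`.
#' `horiuchi_coale` applies a growth correction for a non-stationary
#' population: the open-interval death rate observed in a population
#' growing at rate `r` understates (r > 0) or overstates (r < 0) the
#' stationary rate because growth tilts the age distribution.  The
#' implementation calibrates a Gompertz hazard above the terminal age so
#' that the stable-population death rate with growth `r` matches the
#' observed `m`, then returns the stationary life expectancy of that
#' hazard.  At `r = 0` this reduces exactly to `1/m`; both strategies
#' are strictly decreasing in `m`.
#'
#' @param m Terminal-group death rate, strictly positive.
#' @param strategy `"constant_hazard"` (default) or `"horiuchi_coale"`.
#' @param growth_rate Annual growth rate of the terminal-ages population
#'   (used by `horiuchi_coale` only).
#' @param gompertz_slope Slope of the calibrated Gompertz hazard above the
#'   terminal age (per year of age); default 0.1, a typical old-age value.
#' @return Remaining life expectancy in years.
#' @examples
#' terminal_ex(0.125)                      # 8 years
#' terminal_ex(0.125, "horiuchi_coale", growth_rate = -0.01)
#' @export
terminal_ex <- function(m, strategy = c("constant_hazard", "horiuchi_coale"),
                        growth_rate = 0, gompertz_slope = 0.1) {
  strategy <- match.arg(strategy)
  if (any(m <= 0)) abort("terminal death rate must be strictly positive")
  if (strategy == "constant_hazard") return(1 / m)
  vapply(m, .hc_terminal_ex, numeric(1),
         r = growth_rate, b = gompertz_slope)
}

# Stable-population calibration behind the growth-corrected strategy.
# t is age above the terminal boundary; hazard A*exp(b t); survival
# S(t) = exp(-A/b (exp(b t) - 1)); stable age density ∝ exp(-r t) S(t).
.hc_terminal_ex <- function(m, r, b) {
  t <- seq(0, 60, by = 0.1)
  w <- rep(0.1, length(t)); w[1] <- w[length(t)] <- 0.05  # trapezoid
  rate_for <- function(logA) {
    A <- exp(logA)
    S <- exp(-A / b * (exp(b * t) - 1))
    c_t <- exp(-r * t) * S
    sum(A * exp(b * t) * c_t * w) / sum(c_t * w)
  }
  logA <- uniroot(function(x) rate_for(x) - m,
                  lower = log(m) - 12, upper = log(m) + 4,
                  extendInt = "upX", tol = 1e-10)$root
  A <- exp(logA)
  S <- exp(-A / b * (exp(b * t) - 1))
  sum(S * w)
}

#' Build an abridged life table from a mortality schedule
#'
#' Constructs the full abridged life-table column set (`m`, `a`, `q`, `l`,
#' `d`, `L`, `T`, `e`) on the package age schema with radix 100 000.
#' Person-years in closed intervals are `L = n l(x+n) + a d(x)`; the
#' terminal interval uses `L = l(85) e(85)` with `e(85)` from
#' [terminal_ex()].  `T` is the reverse cumulative sum of `L` and
#' `e = T / l`.
#'
#' @param data A data frame with columns `age_group` and `m` (death rate),
#'   covering every group of `schema`; or a bare numeric vector of rates
#'   in schema order.
#' @param schema Age schema, see [age_schema()].
#' @param terminal_strategy Passed to [terminal_ex()].
#' @param growth_rate Passed to [terminal_ex()] (growth-corrected strategy).
#' @param radix Starting cohort size, default 100 000.
#' @param nax Optional vector of `a` values; default [default_nax()].
#' @return A tibble of class `abridged_life_table` with columns
#'   `age_group`, `age_start`, `n`, `m`, `a`, `q`, `l`, `d`, `L`, `T`, `e`.
#' @examples
#' lt <- build_life_table(rep(0.0125, 19))
#' glance(lt)$e0
#' @export
build_life_table <- function(data, schema = age_schema(),
                             terminal_strategy = "constant_hazard",
                             growth_rate = 0, radix = 1e5, nax = NULL) {
  if (is.numeric(data)) {
    if (length(data) != nrow(schema)) {
      abort("rate vector length does not match the age schema")
    }
    m <- as.numeric(data)
  } else {
    check_age_groups(data$age_group, schema, "mortality schedule")
    m <- data$m[match(schema$age_group, data$age_group)]
  }
  if (anyNA(m)) abort("mortality schedule contains missing rates")
  if (any(m < 0)) abort("death rates must be non-negative")

  k <- nrow(schema)
  n <- schema$age_width
  a <- if (is.null(nax)) default_nax(m, schema) else nax
  q <- mx_to_qx(m, n, a)
  l <- radix * cumprod(c(1, 1 - q[-k]))
  d <- l * q
  L <- numeric(k)
  L[-k] <- n[-k] * (l[-k] - d[-k]) + a[-k] * d[-k]
  e_term <- if (m[k] > 0) {
    terminal_ex(m[k], terminal_strategy, growth_rate = growth_rate)
  } else {
    abort("terminal-group death rate must be positive to close the table")
  }
  L[k] <- l[k] * e_term
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)

  out <- tibble(
    age_group = schema$age_group, age_start = schema$age_start,
    n = n, m = m, a = a, q = q, l = l, d = d, L = L, T = Tx, e = e
  )
  class(out) <- c("abridged_life_table", class(out))
  out
}

#' Partial (temporary) life expectancy over an age range
#'
#' Mean years lived between exact ages `x1` and `x2` by those alive at
#' `x1`: \eqn{(T(x_1) - T(x_2)) / l(x_1)}.  Its maximum is the range
#' width `x2 - x1`, attained when nobody dies in the range.  Both ages
#' must be boundaries of the table's age schema and lie below the open
#' terminal group; remaining life expectancy at 85 is a different
#' quantity, read it from the table's `e` column instead.
#'
#' @param table An `abridged_life_table`.
#' @param x1,x2 Exact ages in years, `x1 < x2`, on schema boundaries.
#' @return Years lived in \[x1, x2), a scalar.
#' @examples
#' lt <- build_life_table(rep(0.0125, 19))
#' temporary_life_expectancy(lt, 0, 5)
#' @export
temporary_life_expectancy <- function(table, x1, x2) {
  starts <- table$age_start
  terminal_start <- starts[!is.finite(table$n)]
  if (x1 >= terminal_start || x2 > terminal_start) {
    abort(paste0("ages must lie at or below the terminal boundary (",
                 terminal_start, "); remaining life expectancy in the open",
                 " group is reported separately in the `e` column"))
  }
  if (x1 >= x2) abort("x1 must be strictly less than x2")
  i1 <- match(x1, starts); i2 <- match(x2, starts)
  if (is.na(i1) || is.na(i2)) {
    abort("x1 and x2 must both be age-schema boundaries")
  }
  (table$T[i1] - table$T[i2]) / table$l[i1]
}

#' @method tidy abridged_life_table
#' @export
tidy.abridged_life_table <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' @method glance abridged_life_table
#' @export
glance.abridged_life_table <- function(x, ...) {
  k <- nrow(x)
  tibble(
    e0 = x$e[1],
    e85 = x$e[k],
    survivors_85 = x$l[k],
    radix = x$l[1],
    n_groups = k
  )
}

# ---- vectorised engine used for simulation ensembles ----------------------
# m_mat: rates, rows = age groups in schema order, cols = independent
# schedules (e.g. America x sex x simulation).  Returns a list of the
# summary quantities needed downstream; avoids building K tibbles.
life_table_engine <- function(m_mat, schema = age_schema(),
                              terminal_strategy = "constant_hazard",
                              growth_rate = 0, radix = 1e5) {
  k <- nrow(schema)
  stopifnot(nrow(m_mat) == k)
  n <- schema$age_width
  a_mat <- matrix(rep(n / 2, ncol(m_mat)), nrow = k)
  a_mat[1, ] <- pmin(0.07 + 1.7 * m_mat[1, ], n[1])
  q <- (n * m_mat) / (1 + (n - a_mat) * m_mat)
  q[k, ] <- 1
  q <- pmin(q, 1)
  surv <- apply(1 - q[-k, , drop = FALSE], 2, cumprod)
  l <- radix * rbind(1, surv)
  d <- l * q
  L <- n * (l - d) + a_mat * d
  e_term <- terminal_ex(pmax(m_mat[k, ], 1e-12), terminal_strategy,
                        growth_rate = growth_rate)
  L[k, ] <- l[k, ] * e_term
  Tx <- apply(L, 2, function(col) rev(cumsum(rev(col))))
  e <- ifelse(l > 0, Tx / l, 0)
  list(l = l, Tx = Tx, e = e, starts = schema$age_start)
}

# partial LE between schema boundaries for every column of an engine result
engine_partial_le <- function(eng, x1, x2) {
  i1 <- match(x1, eng$starts); i2 <- match(x2, eng$starts)
  (eng$Tx[i1, ] - eng$Tx[i2, ]) / eng$l[i1, ]
}
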