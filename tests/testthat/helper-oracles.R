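# Independent, loop-based oracles kept deliberately separate from the
# package's vectorised implementations.

# spreadsheet-style abridged life table: one row at a time, no shared code
oracle_life_table <- function(m, starts, widths, radix = 1e5) {
  k <- length(m)
  a <- q <- l <- d <- L <- Tx <- e <- numeric(k)
  for (i in seq_len(k)) {
    a[i] <- if (i == 1) {
      min(0.07 + 1.7 * m[1], widths[1])
    } else if (is.finite(widths[i])) widths[i] / 2 else NA_real_
    q[i] <- if (is.finite(widths[i])) {
      min(widths[i] * m[i] / (1 + (widths[i] - a[i]) * m[i]), 1)
    } else 1
  }
  l[1] <- radix
  for (i in seq_len(k)) {
    d[i] <- l[i] * q[i]
    if (i < k) l[i + 1] <- l[i] - d[i]
  }
  for (i in seq_len(k - 1)) {
    L[i] <- widths[i] * (l[i] - d[i]) + a[i] * d[i]
  }
  L[k] <- l[k] * (1 / m[k])  # constant-hazard closure
  for (i in k:1) Tx[i] <- L[i] + if (i < k) Tx[i + 1] else 0
  for (i in seq_len(k)) e[i] <- if (l[i] > 0) Tx[i] / l[i] else 0
  data.frame(m = m, a = a, q = q, l = l, d = d, L = L, T = Tx, e = e)
}

# order-statistic percentile with linear interpolation (quantile type 7)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# a gently varying, realistic 19-group mortality schedule used by
# several tests (derived once from a Gompertz-Makeham curve by hand)
hand_schedule <- function() {
  x <- c(0.5, 3, seq(7.5, 82.5, by = 5), 92.5)
  0.0004 + 4e-5 * exp(0.088 * x)
}
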