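#' Abridged age schema
#'
#' The standard abridged grouping used throughout the package: infancy
#' (under 1 year), ages 1-4, five-year groups up to 80-84, and an open
#' terminal group 85+.  Each row carries the interval start, its width
#' `n` (infinite for the terminal group) and the label used in all
#' tabulations.
#'
#' @return A tibble with columns `age_group` (character label),
#'   `age_start` (years), `age_width` (years, `Inf` for the open group).
#' @examples
#' age_schema()
#' @export
age_schema <- function() {
  starts <- c(0, 1, seq(5, 85, by = 5))
  widths <- c(1, 4, rep(5, 16), Inf)
  labels <- c("0", "1-4",
              paste(seq(5, 80, by = 5), seq(9, 84, by = 5), sep = "-"),
              "85+")
  tibble(age_group = labels, age_start = starts, age_width = widths)
}

#' Midpoints of the abridged age groups
#'
#' Used when a hazard function must be evaluated at a representative age
#' for each group.  The open 85+ group uses 92.5 years.
#'
#' @param schema An age schema, as from [age_schema()].
#' @return Numeric vector of midpoints, one per group.
#' @export
age_midpoints <- function(schema = age_schema()) {
  ifelse(is.finite(schema$age_width),
         schema$age_start + schema$age_width / 2,
         schema$age_start + 7.5)
}

# validate that a vector of labels covers the schema exactly once
check_age_groups <- function(x, schema = age_schema(), what = "input") {
  missing <- setdiff(schema$age_group, x)
  if (length(missing) > 0L) {
    abort(paste0(what, " is missing age groups: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
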