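#' Parse dates given at day, month, or year precision
#'
#' Repository metadata and citation dates are frequently month-granular
#' ("March 2005"). Dates are therefore accepted as ISO-8601 prefixes --
#' `YYYY`, `YYYY-MM`, or `YYYY-MM-DD` -- with missing components defaulting
#' to the first month / first day, so `"2005-03"` parses to `2005-03-01`.
#'
#' @param x character vector of ISO-8601 date prefixes.
#' @return a `Date` vector; elements that do not parse are `NA`.
#' @examples
#' parse_partial_date(c("2005-03", "2016-11-01", "1999"))
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  full <- ifelse(grepl("^\\d{4}$", x), paste0(x, "-01-01"),
          ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"),
          ifelse(grepl("^\\d{4}-\\d{2}-\\d{2}$", x), x, NA_character_)))
  as.Date(full, format = "%Y-%m-%d")
}

#' Monthly date grid
#'
#' First-of-month sequence spanning `[start, end]`, the grid used by
#' [overdue_time_series()]. Endpoints are snapped down to the first of
#' their month.
#'
#' @param start,end dates (or ISO-8601 prefix strings), `start <= end`.
#' @return a strictly increasing `Date` vector of month starts.
#' @export
month_grid <- function(start, end) {
  start <- month_floor(as_date_arg(start))
  end <- month_floor(as_date_arg(end))
  if (is.na(start) || is.na(end)) stop("month_grid: unparseable endpoint")
  if (start > end) stop("month_grid: start is after end")
  seq(start, end, by = "month")
}

# Accept Date or partial-date string for user-facing date arguments.
as_date_arg <- function(x) {
  if (inherits(x, "Date")) return(x)
  parse_partial_date(x)
}

month_floor <- function(d) {
  as.Date(format(d, "%Y-%m-01"))
}
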