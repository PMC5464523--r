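#' Earliest citation date per accession
#'
#' @param references classified references (any data frame with
#'   `accession` and `article_publication_date`).
#' @return data frame `accession`, `first_cited` (`Date`), one row per
#'   accession.
#' @export
first_citations <- function(references) {
  if (nrow(references) == 0) {
    return(data.frame(accession = character(),
                      first_cited = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(article_publication_date ~ accession,
                          data = references, FUN = min)
  names(agg)[2L] <- "first_cited"
  agg$first_cited <- as.Date(agg$first_cited,
                             origin = "1970-01-01")
  agg[order(agg$accession), , drop = FALSE]
}

#' Overdue-count time series on a monthly grid
#'
#' For each grid date `t`, counts the datasets already cited in a published
#' article but not yet public: `first_citation(d) <= t` and the release
#' date is absent or after `t`. "First cited" is the earliest publication
#' date among citing articles. Releasing a dataset can only lower the
#' curve, never raise it.
#'
#' @param references classified references (see [first_citations()]); pass
#'   every reference row, or pre-filter to the repository of interest.
#' @param release_dates named `Date` vector mapping accession to release
#'   date (`NA` or absent name = not released), or a data frame with
#'   `accession` and `release_date` columns.
#' @param grid strictly increasing `Date` vector, e.g. [month_grid()];
#'   empty grid is an error.
#' @return data frame of class `overdue_series`: `date`, `count`.
#' @export
overdue_time_series <- function(references, release_dates, grid) {
  if (length(grid) == 0) stop("empty time grid")
  grid <- as.Date(grid)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  if (is.data.frame(release_dates)) {
    release_dates <- stats::setNames(as.Date(release_dates$release_date),
                                     release_dates$accession)
  }
  fc <- first_citations(references)
  rel <- release_dates[match(fc$accession, names(release_dates))]
  rel <- as.Date(rel, origin = "1970-01-01")
  count <- vapply(grid, function(t) {
    sum(fc$first_cited <= t & (is.na(rel) | rel > t))
  }, integer(1))
  structure(data.frame(date = grid, count = count,
                       stringsAsFactors = FALSE),
            class = c("overdue_series", "data.frame"))
}

#' Submission-to-release delay in whole days
#'
#' Calendar-day difference under the month-precision convention: dates
#' supplied at month precision have already been pinned to the first of
#' the month by [parse_partial_date()], so March 2005 to November 2016 is
#' 4,263 days.
#'
#' @param submission,release `Date` vectors (or ISO-8601 prefix strings).
#' @return integer vector of day counts.
#' @export
delay_days <- function(submission, release) {
  as.integer(as_date_arg(release) - as_date_arg(submission))
}

#' Whole calendar years elapsed between submission and release
#'
#' Calendar-year difference, minus one when the release month-day falls
#' before the submission month-day -- the "how many anniversaries have
#' passed" convention, so March 2005 to November 2016 is an 11-year wait.
#'
#' @inheritParams delay_days
#' @return integer vector of whole years.
#' @export
whole_years_elapsed <- function(submission, release) {
  s <- as_date_arg(submission); r <- as_date_arg(release)
  ys <- as.integer(format(s, "%Y")); yr <- as.integer(format(r, "%Y"))
  mds <- format(s, "%m-%d"); mdr <- format(r, "%m-%d")
  yr - ys - ifelse(mdr < mds, 1L, 0L)
}

#' Mean submission-to-release delay per release year
#'
#' Averages [delay_days()] over the datasets released in each calendar
#' year. Records with a release date earlier than their submission date
#' are excluded with a warning and counted in the `excluded` attribute --
#' never silently dropped; records without a release date do not belong to
#' any release year and are ignored. The statistic describes whatever
#' record set it is given (all known datasets, or only cited ones).
#'
#' @param records data frame with `accession`, `submission_date`,
#'   `release_date` (`Date`), e.g. the `records` of a [load_index()].
#' @return data frame of class `delay_stats`: `year`, `mean_delay_days`,
#'   `n`, one row per release year with at least one dataset, ordered by
#'   year; attribute `excluded` counts invariant-violating records.
#' @export
delay_statistics <- function(records) {
  empty <- structure(data.frame(year = integer(),
                                mean_delay_days = numeric(),
                                n = integer(), stringsAsFactors = FALSE),
                     excluded = 0L, class = c("delay_stats", "data.frame"))
  if (nrow(records) == 0) return(empty)
  x <- records[!is.na(records$release_date), , drop = FALSE]
  bad <- x$release_date < x$submission_date
  if (any(bad)) {
    warning(sprintf("excluding %d record(s) with release before submission: %s",
                    sum(bad), paste(x$accession[bad], collapse = ", ")))
    x <- x[!bad, , drop = FALSE]
  }
  if (nrow(x) == 0) {
    attr(empty, "excluded") <- sum(bad)
    return(empty)
  }
  delay <- delay_days(x$submission_date, x$release_date)
  year <- as.integer(format(x$release_date, "%Y"))
  out <- data.frame(year = sort(unique(year)))
  out$mean_delay_days <- vapply(out$year, function(y) {
    mean(delay[year == y])
  }, numeric(1))
  out$n <- vapply(out$year, function(y) sum(year == y), integer(1))
  structure(out, excluded = sum(bad),
            class = c("delay_stats", "data.frame"))
}

#' Detection precision with author errors considered
#'
#' Of `total` flagged candidates, `errors_false_match` are accession-shaped
#' strings that are not dataset citations at all, and `errors_typo` are
#' citations of a wrong accession caused by author typos; both count
#' against precision. Datasets legitimately withheld (incomplete
#' submission, privacy) are genuine dataset citations and count as correct
#' detections -- `withheld_legitimate` is tracked for reporting but does
#' not reduce `correct`.
#'
#' @param total_candidates flagged candidates.
#' @param errors_false_match non-citation string matches.
#' @param errors_typo wrong-accession citations.
#' @param withheld_legitimate correctly detected but unreleasable datasets.
#' @return a `precision_report` list with fields `total_candidates`,
#'   `correct`, `errors_false_match`, `errors_typo`, `withheld_legitimate`,
#'   `precision`; its `format()`/`print()` render the rounded percentage
#'   (e.g. `"97%"`).
#' @export
compute_precision <- function(total_candidates, errors_false_match,
                              errors_typo, withheld_legitimate = 0L) {
  v <- c(total_candidates, errors_false_match, errors_typo,
         withheld_legitimate)
  if (length(v) != 4L || anyNA(v) || any(v < 0) || any(v != floor(v))) {
    stop("counts must be non-negative integers")
  }
  if (total_candidates < 1) stop("total_candidates must be >= 1")
  if (errors_false_match + errors_typo + withheld_legitimate >
        total_candidates) {
    stop("errors plus withheld exceed total_candidates")
  }
  correct <- total_candidates - errors_false_match - errors_typo
  structure(list(total_candidates = as.integer(total_candidates),
                 correct = as.integer(correct),
                 errors_false_match = as.integer(errors_false_match),
                 errors_typo = as.integer(errors_typo),
                 withheld_legitimate = as.integer(withheld_legitimate),
                 precision = correct / total_candidates),
            class = "precision_report")
}

#' @export
format.precision_report <- function(x, ...) {
  sprintf("%d%%", round(100 * x$precision))
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("<precision report: %d/%d correct, precision %.4f (%s)>\n",
              x$correct, x$total_candidates, x$precision, format(x)))
  invisible(x)
}

#' Export an analytics artifact as CSV
#'
#' Time series are written as `date,count`, delay statistics as
#' `year,mean_delay_days,n`, precision reports as labelled `metric,value`
#' rows. UTF-8, header row mandatory, ISO-8601 dates.
#'
#' @param x an `overdue_series`, `delay_stats`, or `precision_report`.
#' @param path output file.
#' @param kind usually inferred from `class(x)`; override to force one of
#'   `"series"`, `"delays"`, `"precision"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(x, path,
                          kind = c("auto", "series", "delays", "precision")) {
  kind <- match.arg(kind)
  if (kind == "auto") {
    kind <- if (inherits(x, "overdue_series")) "series"
            else if (inherits(x, "delay_stats")) "delays"
            else if (inherits(x, "precision_report")) "precision"
            else stop("cannot infer report kind from class: ",
                      paste(class(x), collapse = "/"))
  }
  df <- switch(kind,
    series = data.frame(date = format(x$date), count = x$count),
    delays = data.frame(year = x$year,
                        mean_delay_days = x$mean_delay_days, n = x$n),
    precision = data.frame(
      metric = c("total_candidates", "correct", "errors_false_match",
                 "errors_typo", "withheld_legitimate", "precision",
                 "precision_percent"),
      value = c(x$total_candidates, x$correct, x$errors_false_match,
                x$errors_typo, x$withheld_legitimate,
                format(x$precision), format(x))))
  tryCatch(utils::write.csv(df, path, row.names = FALSE,
                            fileEncoding = "UTF-8"),
           error = function(e) stop("cannot write report to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
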