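#' Load a local release-index snapshot
#'
#' The release index answers "is this accession already known to be
#' publicly released?" from a local metadata snapshot, so that the pipeline
#' only probes the live repository for accessions the snapshot does not
#' know. Presence of an accession in the index implies public release.
#'
#' Two dialects:
#' \describe{
#'   \item{`csv`}{plain CSV with header
#'     `accession,repository,submission_date,release_date,status_hint`;
#'     dates are ISO-8601 prefixes ([parse_partial_date()]); empty
#'     `release_date` means unreleased; `status_hint` is one of `public`,
#'     `private`, `unknown` (empty defaults to `public`, the semantics of a
#'     snapshot hit).}
#'   \item{`snapshot_db`}{a single-file SQLite database laid out like the
#'     GEOmetadb distribution: only the `gse` table's `gse`,
#'     `submission_date`, and `status` columns are read. The snapshot has
#'     no literal release-date column; a `status` of the form
#'     `"Public on Mon DD YYYY"` is parsed as the release-date proxy,
#'     anything else maps to `status_hint = "private"` with no release
#'     date. Requires the DBI and RSQLite packages.}
#' }
#'
#' @param path snapshot file.
#' @param dialect `"csv"` or `"snapshot_db"`.
#' @return a `release_index` object. Malformed rows, or rows violating
#'   `release_date >= submission_date`, are hard errors naming the row.
#' @export
load_index <- function(path, dialect = c("csv", "snapshot_db")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("index file not found: ", path)
  df <- switch(dialect,
               csv = read_index_csv(path),
               snapshot_db = read_index_sqlite(path))
  validate_index(df, path)
}

read_index_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  need <- c("accession", "repository", "submission_date", "release_date",
            "status_hint")
  if (!all(need %in% names(raw))) {
    stop("index CSV must have columns: ", paste(need, collapse = ", "))
  }
  hint <- ifelse(nzchar(trimws(raw$status_hint)), trimws(raw$status_hint),
                 "public")
  data.frame(accession = raw$accession,
             repository = raw$repository,
             submission_date = parse_partial_date(raw$submission_date),
             release_date = parse_partial_date(raw$release_date),
             status_hint = hint,
             stringsAsFactors = FALSE)
}

# GEOmetadb-style layout; column mapping documented in load_index().
read_index_sqlite <- function(path) {
  for (pkg in c("DBI", "RSQLite")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("dialect 'snapshot_db' needs the ", pkg, " package")
    }
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  gse <- DBI::dbGetQuery(con, "SELECT gse, submission_date, status FROM gse")
  release <- parse_public_on(gse$status)
  data.frame(accession = as.character(gse$gse),
             repository = "GEO",
             submission_date = parse_partial_date(gse$submission_date),
             release_date = release,
             status_hint = ifelse(is.na(release), "private", "public"),
             stringsAsFactors = FALSE)
}

# "Public on Mar 01 2005" -> 2005-03-01; locale-independent month lookup.
parse_public_on <- function(status) {
  months <- c(Jan = 1, Feb = 2, Mar = 3, Apr = 4, May = 5, Jun = 6,
              Jul = 7, Aug = 8, Sep = 9, Oct = 10, Nov = 11, Dec = 12)
  m <- regmatches(status,
                  regexec("^Public on ([A-Z][a-z]{2}) (\\d{1,2}) (\\d{4})",
                          as.character(status)))
  vapply(m, function(g) {
    if (length(g) != 4L || !(g[2] %in% names(months))) return(NA_real_)
    as.numeric(as.Date(sprintf("%s-%02d-%02d", g[4], months[[g[2]]],
                               as.integer(g[3]))))
  }, numeric(1)) |> as.Date(origin = "1970-01-01")
}

validate_index <- function(df, path) {
  if (nrow(df) > 0) {
    bad_date <- which(is.na(df$submission_date))
    if (length(bad_date)) {
      stop(sprintf("index %s row %d (%s): unparseable submission_date",
                   path, bad_date[1L], df$accession[bad_date[1L]]))
    }
    inv <- which(!is.na(df$release_date) &
                   df$release_date < df$submission_date)
    if (length(inv)) {
      stop(sprintf("index %s row %d (%s): release_date precedes submission_date",
                   path, inv[1L], df$accession[inv[1L]]))
    }
    pub <- which(df$status_hint == "public" & is.na(df$release_date))
    if (length(pub)) {
      stop(sprintf("index %s row %d (%s): status_hint 'public' without release_date",
                   path, pub[1L], df$accession[pub[1L]]))
    }
    if (anyDuplicated(df$accession)) {
      stop("index ", path, " has duplicate accession: ",
           df$accession[duplicated(df$accession)][1L])
    }
  }
  rownames(df) <- NULL
  structure(list(records = df, source = path), class = "release_index")
}

#' Look up one accession in a release index
#'
#' Exact canonical-string match (case-sensitive, no normalisation). A hit
#' short-circuits probing in the pipeline; not-found is a value (`NULL`),
#' not an error, and triggers a live probe downstream.
#'
#' @param index a [load_index()] object.
#' @param accession accession string.
#' @return the matching release record as a one-row data frame, or `NULL`.
#' @export
index_lookup <- function(index, accession) {
  stopifnot(inherits(index, "release_index"), length(accession) == 1L)
  i <- match(accession, index$records$accession)
  if (is.na(i)) return(NULL)
  index$records[i, , drop = FALSE]
}

#' @export
print.release_index <- function(x, ...) {
  cat(sprintf("<release index: %d record(s) from %s>\n",
              nrow(x$records), x$source))
  invisible(x)
}
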