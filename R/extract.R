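#' Declare an accession-number pattern
#'
#' An accession pattern is a repository label plus a literal uppercase
#' prefix and a bounded digit run: GEO series accessions are `GSE` followed
#' by digits, SRA experiment accessions `SRX` followed by digits. The digit
#' cap (default 8) guards against pathological digit runs; real GEO/SRA
#' identifiers are well under it. Leading zeros are preserved verbatim --
#' the accession is an opaque key at the repository, never a number.
#'
#' @param repository repository label, e.g. `"GEO"` or `"SRA"`.
#' @param prefix literal uppercase alphabetic prefix, e.g. `"GSE"`.
#' @param digit_min,digit_max bounds on the digit-run length,
#'   `1 <= digit_min <= digit_max`.
#' @return an `accession_pattern` object.
#' @seealso [compile_patterns()], [default_patterns()]
#' @export
accession_pattern <- function(repository, prefix, digit_min = 1L,
                              digit_max = 8L) {
  stopifnot(is.character(repository), length(repository) == 1L,
            nzchar(repository))
  if (!grepl("^[A-Z]+$", prefix)) {
    stop("prefix must be non-empty uppercase alphabetic: '", prefix, "'")
  }
  digit_min <- as.integer(digit_min); digit_max <- as.integer(digit_max)
  if (digit_min < 1L || digit_min > digit_max) {
    stop("need 1 <= digit_min <= digit_max")
  }
  structure(list(repository = repository, prefix = prefix,
                 digit_min = digit_min, digit_max = digit_max),
            class = "accession_pattern")
}

#' Default pattern registry: GEO series and SRA experiments
#'
#' @return list of [accession_pattern()] specs for `GSE` (GEO) and `SRX`
#'   (SRA) accessions.
#' @export
default_patterns <- function() {
  list(accession_pattern("GEO", "GSE"),
       accession_pattern("SRA", "SRX"))
}

#' Compile accession patterns into a scanning registry
#'
#' @param specs non-empty list of [accession_pattern()] objects; duplicate
#'   (repository, prefix) pairs are a hard error. Two repositories may share
#'   the same prefix text: matches are then reported once per repository.
#' @param case_insensitive match prefixes case-insensitively (default off;
#'   accession prefixes are printed uppercase).
#' @return an `accession_registry`.
#' @export
compile_patterns <- function(specs = default_patterns(),
                             case_insensitive = FALSE) {
  if (!is.list(specs) || length(specs) == 0L) {
    stop("specs must be a non-empty list of accession_pattern objects")
  }
  if (inherits(specs, "accession_pattern")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1), "accession_pattern")
  if (!all(ok)) stop("all specs must be accession_pattern objects")
  keys <- vapply(specs, function(s) paste(s$repository, s$prefix), "")
  if (anyDuplicated(keys)) {
    stop("duplicate (repository, prefix) pair: ",
         keys[duplicated(keys)][1L])
  }
  regexes <- vapply(specs, function(s) {
    sprintf("(?<![A-Za-z0-9])%s[0-9]{%d,%d}(?![A-Za-z0-9])",
            s$prefix, s$digit_min, s$digit_max)
  }, "")
  structure(list(specs = specs, regexes = regexes,
                 case_insensitive = isTRUE(case_insensitive)),
            class = "accession_registry")
}

#' @export
print.accession_registry <- function(x, ...) {
  cat("<accession registry>\n")
  for (s in x$specs) {
    cat(sprintf("  %-4s %s[0-9]{%d,%d}\n", s$repository, s$prefix,
                s$digit_min, s$digit_max))
  }
  invisible(x)
}

#' Extract candidate accession numbers from one article
#'
#' Scans the raw article text with the registry's patterns and returns all
#' boundary-respecting, maximal matches in left-to-right span order. The
#' token-boundary rule: a match is rejected when the character before the
#' prefix or the character after the digit run is alphanumeric, so
#' `"XGSE123"` and `"GSE456ABC"` yield nothing while `"GSE12345."` matches.
#' A bare `GSE[0-9]+` would fire inside longer identifiers; boundary
#' handling is what keeps the false-match rate low. Extraction is purely
#' lexical -- it cannot tell a dataset citation from an accession-shaped
#' string used as something else (a soil-sample code, say); that is what the
#' context window and the downstream repository probe are for.
#'
#' @param article one corpus row (or any list with `article_id` and `text`).
#' @param registry an [compile_patterns()] registry.
#' @param context_width characters of context captured on each side of a
#'   match (clipped at text ends); default 60, enough for manual curation
#'   of spurious hits.
#' @return data frame with columns `accession`, `repository`, `article_id`,
#'   `start`, `end` (0-based half-open character span: `substr(text,
#'   start+1, end)` is the accession), `context`; zero rows for empty text.
#' @export
extract_candidates <- function(article, registry = compile_patterns(),
                               context_width = 60L) {
  stopifnot(inherits(registry, "accession_registry"))
  text <- article$text
  id <- article$article_id
  stopifnot(length(text) == 1L, length(id) == 1L)
  empty <- data.frame(accession = character(), repository = character(),
                      article_id = character(), start = integer(),
                      end = integer(), context = character(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  rows <- list()
  for (k in seq_along(registry$specs)) {
    spec <- registry$specs[[k]]
    m <- gregexpr(registry$regexes[k], text, perl = TRUE,
                  ignore.case = registry$case_insensitive)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    rows[[length(rows) + 1L]] <- data.frame(
      accession = substring(text, m, m + len - 1L),
      repository = spec$repository,
      article_id = id,
      start = as.integer(m) - 1L,
      end = as.integer(m) + len - 1L,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$repository), , drop = FALSE]
  nc <- nchar(text)
  out$context <- substring(text, pmax(1L, out$start + 1L - context_width),
                           pmin(nc, out$end + context_width))
  rownames(out) <- NULL
  out
}

#' Collapse mention-level candidates to unique article/accession references
#'
#' The monitoring question is per dataset, not per mention: an accession
#' cited three times in one article is one reference. Keeps the earliest
#' span as the representative mention; output is ordered by article then
#' accession. Idempotent.
#'
#' @param candidates data frame from [extract_candidates()] (rows from
#'   several articles may be concatenated).
#' @return data frame with one row per distinct
#'   (article_id, repository, accession) triple, same columns.
#' @export
deduplicate <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  o <- order(candidates$article_id, candidates$accession, candidates$start)
  x <- candidates[o, , drop = FALSE]
  key <- paste(x$article_id, x$repository, x$accession, sep = "\r")
  x <- x[!duplicated(key), , drop = FALSE]
  x <- x[order(x$article_id, x$accession, x$repository), , drop = FALSE]
  rownames(x) <- NULL
  x
}
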