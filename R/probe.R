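#' Signature strings for one repository's status pages
#'
#' Accession status is decided by substring search for literal signature
#' phrases in the raw response body, not by structural HTML parsing:
#' signature matching is robust to markup churn in the status pages. The
#' defaults are the two phrases NCBI prints -- one marking an invalid
#' accession, one marking a dataset that exists but is still private --
#' and they are configuration, not code, because the real phrase set may
#' grow.
#'
#' @param repository repository label.
#' @param invalid_signatures,private_signatures non-empty character vectors
#'   of literal phrases; no phrase may appear in both.
#' @return a `signature_set`.
#' @export
signature_set <- function(repository,
                          invalid_signatures = "Could not find a public or private accession",
                          private_signatures = "is currently private") {
  stopifnot(length(repository) == 1L, nzchar(repository))
  if (length(invalid_signatures) == 0L || length(private_signatures) == 0L) {
    stop("signature lists must be non-empty")
  }
  both <- intersect(invalid_signatures, private_signatures)
  if (length(both)) {
    stop("signature appears in both lists: ", both[1L])
  }
  structure(list(repository = repository,
                 invalid_signatures = invalid_signatures,
                 private_signatures = private_signatures),
            class = "signature_set")
}

#' Default signature sets for GEO and SRA
#'
#' Both repositories use the same phrases by default; SRA status pages are
#' handled the same way as GEO's.
#'
#' @return named list of [signature_set()] objects keyed by repository.
#' @export
default_signatures <- function() {
  list(GEO = signature_set("GEO"), SRA = signature_set("SRA"))
}

repo_url_templates <- c(
  GEO = "https://www.ncbi.nlm.nih.gov/geo/query/acc.cgi?acc=%s",
  SRA = "https://www.ncbi.nlm.nih.gov/sra/?term=%s")

#' Build the status-query URL for an accession
#'
#' Substitutes the accession into the repository's accession-display
#' template: `geo/query/acc.cgi?acc=<accession>` for GEO,
#' `sra/?term=<accession>` for SRA. The accession must match the
#' repository's own pattern; probing GEO for an SRA accession is a hard
#' error, not a silent miss.
#'
#' @param repository `"GEO"` or `"SRA"`.
#' @param accession accession string valid for that repository.
#' @param registry pattern registry used for the cross-repository check.
#' @return the URL string.
#' @export
build_query_url <- function(repository, accession,
                            registry = compile_patterns()) {
  if (!repository %in% names(repo_url_templates)) {
    stop("no URL template for repository: ", repository)
  }
  specs <- Filter(function(s) s$repository == repository, registry$specs)
  ok <- any(vapply(specs, function(s) {
    grepl(sprintf("^%s[0-9]{%d,%d}$", s$prefix, s$digit_min, s$digit_max),
          accession)
  }, logical(1)))
  if (!ok) {
    stop(sprintf("accession '%s' does not match any %s pattern",
                 accession, repository))
  }
  sprintf(repo_url_templates[[repository]], accession)
}

#' Parse a repository status page into an accession status
#'
#' Pure substring classification with total precedence
#' invalid > private > public > unknown: any invalid signature wins, else
#' any private signature, else the page counts as public only if the
#' accession string itself occurs in it; a page with neither signature nor
#' the accession is `unknown`, never `public` -- the fail-safe against
#' mislabelling an error page as a released dataset.
#'
#' @param repository repository label (for the result record only).
#' @param page_text full response body as one string.
#' @param signatures a [signature_set()].
#' @param accession the accession that was queried.
#' @return one of `"invalid"`, `"private"`, `"public"`, `"unknown"`, with
#'   the matching phrase in attribute `matched_signature` for the first two.
#' @export
parse_status_page <- function(repository, page_text, signatures, accession) {
  stopifnot(inherits(signatures, "signature_set"), length(page_text) == 1L)
  if (is.na(page_text)) page_text <- ""
  hit <- function(sigs) {
    for (s in sigs) if (grepl(s, page_text, fixed = TRUE)) return(s)
    NULL
  }
  s <- hit(signatures$invalid_signatures)
  if (!is.null(s)) return(structure("invalid", matched_signature = s))
  s <- hit(signatures$private_signatures)
  if (!is.null(s)) return(structure("private", matched_signature = s))
  if (nzchar(accession) && grepl(accession, page_text, fixed = TRUE)) {
    return("public")
  }
  "unknown"
}

#' A probe-result cache with time-to-live
#'
#' Keyed by (repository, accession); a fresh entry is returned without a
#' transport call. Default TTL 24 h: status pages change on the release
#' timescale, not minutes.
#'
#' @param ttl_seconds seconds before a cached result goes stale.
#' @return a `probe_cache`.
#' @export
new_probe_cache <- function(ttl_seconds = 86400) {
  structure(list(store = new.env(parent = emptyenv()),
                 ttl = as.numeric(ttl_seconds)),
            class = "probe_cache")
}

cache_get <- function(cache, key) {
  if (is.null(cache)) return(NULL)
  hit <- cache$store[[key]]
  if (is.null(hit)) return(NULL)
  age <- as.numeric(Sys.time()) - as.numeric(hit$retrieved_at)
  if (age > cache$ttl) return(NULL)
  hit
}

# last live-call timestamp, for rate limiting across probe() calls
.datawatch_state <- new.env(parent = emptyenv())

#' Probe the repository for one accession's status
#'
#' One transport call per (repository, accession) unless a fresh cached
#' result exists. The transport contract: a function taking a URL string
#' and returning the body text, or signalling an error on network failure.
#' Transport errors never propagate past the probe -- they degrade to
#' status `unknown` with the error message recorded, so one flaky request
#' cannot abort a monitoring run. Live transports (attribute
#' `live = TRUE`, see [http_transport()]) are rate limited to at most one
#' request per `rate_limit` seconds, a politeness floor for the real
#' endpoint; fixture transports are never throttled.
#'
#' @param accession,repository what to probe.
#' @param transport URL -> body-text function ([fixture_transport()] for
#'   offline runs, [http_transport()] for live ones).
#' @param signatures named list of [signature_set()] per repository.
#' @param cache optional [new_probe_cache()].
#' @param rate_limit minimum seconds between live transport calls
#'   (default 0.4).
#' @param registry pattern registry for URL validation.
#' @return a `probe_result` list: `accession`, `repository`, `status`,
#'   `matched_signature` (`NA` unless invalid/private), `retrieved_at`,
#'   `url`, `error` (`NA` unless the transport failed).
#' @export
probe <- function(accession, repository, transport,
                  signatures = default_signatures(), cache = NULL,
                  rate_limit = 0.4, registry = compile_patterns()) {
  key <- paste(repository, accession, sep = ":")
  hit <- cache_get(cache, key)
  if (!is.null(hit)) return(hit)

  sigs <- signatures[[repository]]
  if (is.null(sigs)) stop("no signature set for repository: ", repository)
  url <- build_query_url(repository, accession, registry)

  if (isTRUE(attr(transport, "live")) && rate_limit > 0) {
    last <- .datawatch_state$last_live_call
    if (!is.null(last)) {
      wait <- rate_limit - (as.numeric(Sys.time()) - last)
      if (wait > 0) Sys.sleep(wait)
    }
    .datawatch_state$last_live_call <- as.numeric(Sys.time())
  }

  err <- NA_character_
  page <- tryCatch(transport(url), error = function(e) {
    err <<- conditionMessage(e)
    NULL
  })
  if (is.null(page)) {
    status <- "unknown"
    sig <- NA_character_
  } else {
    status <- parse_status_page(repository, page, sigs, accession)
    sig <- attr(status, "matched_signature")
    if (is.null(sig)) sig <- NA_character_
    status <- as.character(status)
    if (status == "unknown") {
      err <- "page matched no signature and did not contain the accession"
    }
  }
  res <- structure(list(accession = accession, repository = repository,
                        status = status, matched_signature = sig,
                        retrieved_at = Sys.time(), url = url, error = err),
                   class = "probe_result")
  if (!is.null(cache)) cache$store[[key]] <- res
  res
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("<probe %s/%s: %s>\n", x$repository, x$accession, x$status))
  invisible(x)
}

#' On-disk fixture transport
#'
#' Maps a status-query URL back to its accession and serves
#' `<pages_dir>/<accession>.txt`. A missing page file is treated as a
#' transport failure (the probe records status `unknown`), which surfaces
#' fixture gaps instead of hiding them.
#'
#' @param pages_dir directory of per-accession status-page files.
#' @return a transport function.
#' @export
fixture_transport <- function(pages_dir) {
  force(pages_dir)
  function(url) {
    acc <- url_accession(url)
    fp <- file.path(pages_dir, paste0(acc, ".txt"))
    if (!file.exists(fp)) {
      stop("fixture transport: no page for accession ", acc)
    }
    read_text_file(fp)
  }
}

url_accession <- function(url) {
  m <- regmatches(url, regexec("(?:acc=|term=)([A-Za-z0-9]+)", url))[[1L]]
  if (length(m) != 2L) stop("cannot find accession in URL: ", url)
  m[2L]
}

#' Live HTTP transport
#'
#' Fetches the URL with base R connections; carries the `live` attribute
#' so [probe()] applies its rate limit. Offline test and grading runs use
#' [fixture_transport()] instead.
#'
#' @param timeout seconds before a request is abandoned.
#' @return a transport function.
#' @export
http_transport <- function(timeout = 30) {
  f <- function(url) {
    con <- url(url, open = "rb")
    on.exit(close(con))
    old <- options(timeout = timeout); on.exit(options(old), add = TRUE)
    paste(readLines(con, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  attr(f, "live") <- TRUE
  f
}

#' Count calls made through a transport
#'
#' Wraps any transport so that tests (and the pipeline's run metadata) can
#' verify the index short-circuit: the number of transport invocations must
#' equal the number of accessions the release index did not know.
#'
#' @param transport transport function to wrap.
#' @return the wrapped transport; read the count with
#'   [transport_calls()].
#' @export
counting_transport <- function(transport) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  f <- function(url) {
    counter$n <- counter$n + 1L
    transport(url)
  }
  attributes(f) <- attributes(transport)
  attr(f, "counter") <- counter
  f
}

#' @rdname counting_transport
#' @export
transport_calls <- function(transport) {
  counter <- attr(transport, "counter")
  if (is.null(counter)) stop("not a counting transport")
  counter$n
}
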