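#' Classify one article/accession reference
#'
#' The classification contract: an index hit means the dataset is already
#' public (`released`, evidence `index_hit`) and is never probed; an index
#' miss is resolved by the probe -- `public` maps to `released`, `private`
#' to `overdue` (the dataset remains private although a published article
#' cites it), `invalid` to `invalid`, and a failed or uninterpretable probe
#' stays `unknown`. Supplying both an index hit and a probe result breaks
#' the pipeline contract and is a hard error.
#'
#' @param reference one-row data frame from [deduplicate()] (needs
#'   `accession`, `repository`, `article_id`).
#' @param index_result [index_lookup()] result: a record or `NULL`.
#' @param probe_result [probe()] result, present iff `index_result` is
#'   `NULL`.
#' @param article_date the citing article's publication date, copied
#'   through for time-series use.
#' @return one-row data frame: `accession`, `repository`, `article_id`,
#'   `article_publication_date`, `classification`, `release_date`,
#'   `evidence`.
#' @export
classify_reference <- function(reference, index_result, probe_result,
                               article_date) {
  if (!is.null(index_result) && !is.null(probe_result)) {
    stop("pipeline contract breach: both index hit and probe result for ",
         reference$accession)
  }
  if (is.null(index_result) && is.null(probe_result)) {
    stop("need either an index hit or a probe result for ",
         reference$accession)
  }
  if (!is.null(index_result)) {
    classification <- "released"
    evidence <- "index_hit"
    release_date <- index_result$release_date
  } else {
    classification <- switch(probe_result$status,
                             public = "released",
                             private = "overdue",
                             invalid = "invalid",
                             unknown = "unknown",
                             stop("unexpected probe status: ",
                                  probe_result$status))
    evidence <- paste0("probe_", probe_result$status)
    release_date <- as.Date(NA)
  }
  data.frame(accession = reference$accession,
             repository = reference$repository,
             article_id = reference$article_id,
             article_publication_date = as_date_arg(article_date),
             classification = classification,
             release_date = release_date,
             evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Run the full overdue-dataset monitor over a corpus
#'
#' Orchestrates extraction, the release-index short circuit, repository
#' probing, and classification: every article is scanned for accession
#' candidates, mentions are collapsed to unique (article, accession)
#' references, each unique accession is resolved once -- by index lookup
#' where possible, by a single probe otherwise -- and every reference is
#' classified. Overdue status is evaluated at run time, not publication
#' time: any still-private dataset cited by an article published on or
#' before `run_date` is overdue. Articles dated after `run_date` are
#' excluded with a warning (degenerate input guard). Probe errors degrade
#' to `unknown`; corpus or index load errors propagate.
#'
#' @param corpus a [load_corpus()] data frame.
#' @param index a [load_index()] object, or `NULL` for no short circuit.
#' @param transport probe transport ([fixture_transport()] or
#'   [http_transport()]).
#' @param config run configuration, see [default_config()].
#' @param run_date date of the monitoring run (default today).
#' @param store optional run-store directory; when given, the result is
#'   persisted with [write_run()].
#' @param cache optional [new_probe_cache()] shared across runs.
#' @return a `datawatch_run`: `references` (all classified references),
#'   `overdue` (the overdue list, sorted by accession, with columns
#'   `accession,repository,article_id,article_publication_date,evidence`),
#'   `counts` per classification, `n_transport_calls`, `run_date`,
#'   `n_articles`, `excluded_articles`.
#' @export
run_monitor <- function(corpus, index, transport,
                        config = default_config(),
                        run_date = Sys.Date(), store = NULL, cache = NULL) {
  run_date <- as_date_arg(run_date)
  registry <- compile_patterns(config$patterns,
                               case_insensitive = config$case_insensitive)
  signatures <- config$signatures

  future <- corpus$publication_date > run_date
  if (any(future)) {
    warning(sprintf("excluding %d article(s) dated after the run date: %s",
                    sum(future),
                    paste(corpus$article_id[future], collapse = ", ")))
    corpus <- corpus[!future, , drop = FALSE]
  }

  cands <- lapply(seq_len(nrow(corpus)), function(i) {
    extract_candidates(corpus[i, ], registry,
                       context_width = config$context_width)
  })
  cands <- if (length(cands)) do.call(rbind, cands) else NULL
  refs <- if (is.null(cands)) {
    data.frame(accession = character(), repository = character(),
               article_id = character(), start = integer(),
               end = integer(), context = character(),
               stringsAsFactors = FALSE)
  } else {
    deduplicate(cands)
  }

  transport <- counting_transport(transport)
  pub_date <- corpus$publication_date[match(refs$article_id,
                                            corpus$article_id)]

  # resolve each unique accession once per run
  ukey <- !duplicated(paste(refs$repository, refs$accession))
  resolution <- list()
  for (i in which(ukey)) {
    acc <- refs$accession[i]
    repo <- refs$repository[i]
    hit <- if (is.null(index)) NULL else index_lookup(index, acc)
    pr <- if (is.null(hit)) {
      probe(acc, repo, transport, signatures = signatures, cache = cache,
            rate_limit = config$rate_limit, registry = registry)
    } else {
      NULL
    }
    resolution[[paste(repo, acc)]] <- list(index = hit, probe = pr)
  }

  rows <- lapply(seq_len(nrow(refs)), function(i) {
    r <- resolution[[paste(refs$repository[i], refs$accession[i])]]
    classify_reference(refs[i, ], r$index, r$probe, pub_date[i])
  })
  references <- if (length(rows)) do.call(rbind, rows) else
    classify_template()
  rownames(references) <- NULL

  overdue <- references[references$classification == "overdue",
                        c("accession", "repository", "article_id",
                          "article_publication_date", "evidence"),
                        drop = FALSE]
  overdue <- overdue[order(overdue$accession, overdue$article_id), ,
                     drop = FALSE]
  rownames(overdue) <- NULL

  counts <- table(factor(references$classification,
                         levels = c("released", "overdue", "invalid",
                                    "unknown")))
  run <- structure(list(references = references, overdue = overdue,
                        counts = counts,
                        n_transport_calls = transport_calls(transport),
                        run_date = run_date,
                        n_articles = nrow(corpus),
                        excluded_articles = sum(future)),
                   class = "datawatch_run")
  if (!is.null(store)) write_run(run, store)
  run
}

classify_template <- function() {
  data.frame(accession = character(), repository = character(),
             article_id = character(),
             article_publication_date = as.Date(character()),
             classification = character(),
             release_date = as.Date(character()),
             evidence = character(), stringsAsFactors = FALSE)
}

#' @export
print.datawatch_run <- function(x, ...) {
  cat(sprintf("<datawatch run %s: %d article(s), %d reference(s)>\n",
              format(x$run_date), x$n_articles, nrow(x$references)))
  print(x$counts)
  cat(sprintf("  transport calls: %d\n", x$n_transport_calls))
  invisible(x)
}

#' Persist a monitoring run to the run store
#'
#' The run store is an append-only directory of per-run subdirectories in
#' delimited formats -- desk-scale and inspectable, no database server.
#' Each run directory holds `references.csv`, `overdue.csv`, and
#' `meta.json`.
#'
#' @param run a `datawatch_run`.
#' @param store store directory (created if needed).
#' @param run_id subdirectory name; defaults to a timestamp, but passing an
#'   explicit id keeps reruns reproducible.
#' @return the run directory path, invisibly.
#' @export
write_run <- function(run, store, run_id = NULL) {
  if (is.null(run_id)) {
    run_id <- format(Sys.time(), "run-%Y%m%d-%H%M%OS3")
  }
  dir.create(store, showWarnings = FALSE, recursive = TRUE)
  run_dir <- file.path(store, run_id)
  if (dir.exists(run_dir)) stop("run store is append-only; ", run_dir,
                                " already exists")
  dir.create(run_dir)
  utils::write.csv(run$references, file.path(run_dir, "references.csv"),
                   row.names = FALSE)
  utils::write.csv(run$overdue, file.path(run_dir, "overdue.csv"),
                   row.names = FALSE)
  meta <- list(run_date = format(run$run_date),
               n_articles = run$n_articles,
               excluded_articles = run$excluded_articles,
               n_transport_calls = run$n_transport_calls,
               counts = as.list(run$counts))
  jsonlite::write_json(meta, file.path(run_dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(run_dir)
}

#' Read a persisted monitoring run
#'
#' @param run_dir a run directory written by [write_run()].
#' @return a `datawatch_run` (without transport internals).
#' @export
read_run <- function(run_dir) {
  refs <- utils::read.csv(file.path(run_dir, "references.csv"),
                          colClasses = "character")
  if (nrow(refs) == 0) {
    refs <- classify_template()
  } else {
    refs$article_publication_date <- as.Date(refs$article_publication_date)
    refs$release_date <- as.Date(refs$release_date)
  }
  overdue <- utils::read.csv(file.path(run_dir, "overdue.csv"),
                             colClasses = "character")
  meta <- jsonlite::read_json(file.path(run_dir, "meta.json"))
  structure(list(references = refs, overdue = overdue,
                 counts = table(factor(refs$classification,
                                       levels = c("released", "overdue",
                                                  "invalid", "unknown"))),
                 n_transport_calls = meta$n_transport_calls,
                 run_date = as.Date(meta$run_date),
                 n_articles = meta$n_articles,
                 excluded_articles = meta$excluded_articles),
            class = "datawatch_run")
}

#' Diff two monitoring runs of the same corpus scope
#'
#' Tracks release progress between runs at the accession level:
#' `newly_released` are accessions overdue in the previous run and released
#' in the current one, `newly_overdue` are overdue now but were not overdue
#' before (including accessions absent before), `still_overdue` the
#' persistent backlog.
#'
#' @param previous,current `datawatch_run` objects or run-store paths.
#' @return list of three sorted accession character vectors:
#'   `newly_overdue`, `newly_released`, `still_overdue`.
#' @export
diff_runs <- function(previous, current) {
  as_run <- function(x) if (inherits(x, "datawatch_run")) x else read_run(x)
  previous <- as_run(previous); current <- as_run(current)
  od <- function(run) unique(run$references$accession[
    run$references$classification == "overdue"])
  rel <- function(run) unique(run$references$accession[
    run$references$classification == "released"])
  o1 <- od(previous); o2 <- od(current)
  list(newly_overdue = sort(setdiff(o2, o1)),
       newly_released = sort(intersect(o1, rel(current))),
       still_overdue = sort(intersect(o1, o2)))
}
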