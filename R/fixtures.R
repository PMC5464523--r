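#' Specification for a synthetic monitoring world
#'
#' The generator emulates the three real inputs of an overdue-dataset
#' monitor -- a full-text corpus, a release-index snapshot, and repository
#' status pages -- with known ground truth. Defaults mirror the scale of a
#' desk-size audit: a few hundred articles and datasets, about 30% of
#' datasets still private, a ~3% author-typo rate and a ~0.2% spurious-match
#' rate per citation/article (the observed failure modes of lexical
#' accession detection: citing a wrong accession, and accession-shaped
#' strings that are not dataset citations at all, such as a soil-sample
#' code).
#'
#' @param n_articles,n_datasets world size (non-negative integers).
#' @param fraction_private fraction of datasets still private in `[0,1]`.
#' @param typo_rate per-citation probability that the embedded accession is
#'   a corrupted (wrong) one, in `[0,1]`.
#' @param spurious_rate per-article probability of one spurious
#'   accession-shaped non-citation string, in `[0,1]`.
#' @param date_range character or `Date` length-2 vector, submission and
#'   publication dates are drawn uniformly within it.
#' @param seed integer; one pseudo-random stream keyed by it drives every
#'   choice, so a fixture is byte-identical across runs and platforms.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_articles = 200L, n_datasets = 300L,
                         fraction_private = 0.3, typo_rate = 0.03,
                         spurious_rate = 0.002,
                         date_range = c("2010-01-01", "2016-12-31"),
                         seed = 1L) {
  n_articles <- as.integer(n_articles); n_datasets <- as.integer(n_datasets)
  if (n_articles < 0L || n_datasets < 0L) stop("counts must be >= 0")
  for (r in c(fraction_private, typo_rate, spurious_rate)) {
    if (is.na(r) || r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  date_range <- as_date_arg(date_range)
  if (length(date_range) != 2L || anyNA(date_range) ||
        date_range[1L] > date_range[2L]) {
    stop("date_range must be two ordered dates")
  }
  if (typo_rate > 0 && n_datasets == 0L) {
    stop("impossible spec: typo_rate > 0 with no datasets to mis-cite")
  }
  structure(list(n_articles = n_articles, n_datasets = n_datasets,
                 fraction_private = fraction_private,
                 typo_rate = typo_rate, spurious_rate = spurious_rate,
                 date_range = date_range, seed = as.integer(seed)),
            class = "fixture_spec")
}

with_rng_seed <- function(seed, fn) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  fn()
}

citation_templates <- c(
  "The expression profiles generated in this study have been deposited in the repository under accession %s and are freely browsable.",
  "Raw data supporting these findings are available from the archive under accession number %s.",
  "All processed datasets described here were submitted under accession %s as required by the journal's data policy.")

spurious_template <- "Soil sample %s was collected from the upper horizon of the field site and stored at -80C."

filler_sentences <- c(
  "Differential analysis was performed with standard linear models and moderated statistics.",
  "Samples were processed in randomized batches to limit technical confounding.",
  "We thank the sequencing core for library preparation and quality control.",
  "Pathway enrichment was assessed against the background of all expressed genes.")

#' Generate a synthetic corpus, release index, and status pages
#'
#' Writes a complete offline monitoring world under `out_dir`:
#' \itemize{
#'   \item `manifest.csv` + `texts/` -- articles embedding true citations,
#'     typo'd citations (valid-format accessions that exist nowhere, served
#'     an invalid-signature page), and spurious accession-shaped strings in
#'     non-dataset sentences (these correspond to real-but-private
#'     repository entries, reproducing the false-positive mode where a
#'     private accession string is used as something other than a dataset
#'     citation);
#'   \item `index.csv` -- release-index rows for every public dataset;
#'   \item `pages/` -- one status-page file per accession: public pages
#'     contain the accession, private pages the private signature, unknown
#'     accessions the invalid signature;
#'   \item `truth_datasets.csv`, `truth_candidates.csv` -- the ground
#'     truth, with every embedded candidate labelled `true_citation`,
#'     `typo`, or `spurious`.
#' }
#' Byte-identical for a fixed seed (no timestamps, single seeded RNG
#' stream, deterministic ordering).
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created; must not already contain a
#'   manifest).
#' @return a `datawatch_fixture`: paths (`dir`, `manifest`, `text_root`,
#'   `index`, `pages`) plus `truth` (`datasets`, `candidates`,
#'   `overdue_accessions`) and the `spec`.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  text_root <- file.path(out_dir, "texts")
  pages_dir <- file.path(out_dir, "pages")
  dir.create(text_root, showWarnings = FALSE)
  dir.create(pages_dir, showWarnings = FALSE)

  world <- with_rng_seed(spec$seed, function() build_world(spec))

  # corpus
  ids <- world$articles$article_id
  man <- data.frame(article_id = ids,
                    publication_date = format(world$articles$publication_date),
                    text_path = if (length(ids)) paste0(ids, ".txt")
                                else character(),
                    stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(world$articles))) {
    writeLines(world$articles$text[i],
               file.path(text_root, man$text_path[i]), useBytes = TRUE)
  }

  # release index: every public dataset
  ds <- world$datasets
  pub <- ds[!ds$private, , drop = FALSE]
  idx <- data.frame(accession = pub$accession, repository = pub$repository,
                    submission_date = format(pub$submission_date),
                    release_date = format(pub$release_date),
                    status_hint = rep("public", nrow(pub)),
                    stringsAsFactors = FALSE)
  utils::write.csv(idx, file.path(out_dir, "index.csv"), row.names = FALSE)

  # status pages
  write_page <- function(acc, body) {
    writeLines(body, file.path(pages_dir, paste0(acc, ".txt")),
               useBytes = TRUE)
  }
  for (i in seq_len(nrow(ds))) {
    if (ds$private[i]) {
      write_page(ds$accession[i], sprintf(
        "<html><body>Accession %s is currently private and is scheduled to be released once the citing manuscript is published.</body></html>",
        ds$accession[i]))
    } else {
      write_page(ds$accession[i], sprintf(
        "<html><body>Series %s - public record. Status: Public on %s. Samples listed below.</body></html>",
        ds$accession[i], format(ds$release_date[i])))
    }
  }
  for (acc in world$typo_accessions) {
    write_page(acc, sprintf(
      "<html><body>Error: Could not find a public or private accession \"%s\".</body></html>",
      acc))
  }
  for (acc in world$spurious_accessions) {
    write_page(acc, sprintf(
      "<html><body>Accession %s is currently private and awaiting curation.</body></html>",
      acc))
  }

  # ground truth
  truth_ds <- data.frame(accession = ds$accession,
                         repository = ds$repository,
                         submission_date = ds$submission_date,
                         release_date = ds$release_date,
                         private = ds$private,
                         cited_by = ds$cited_by, stringsAsFactors = FALSE)
  utils::write.csv(transform(truth_ds,
                             submission_date = format(submission_date),
                             release_date = ifelse(is.na(release_date), "",
                                                   format(release_date))),
                   file.path(out_dir, "truth_datasets.csv"),
                   row.names = FALSE)
  utils::write.csv(world$candidates,
                   file.path(out_dir, "truth_candidates.csv"),
                   row.names = FALSE)

  cited <- nzchar(truth_ds$cited_by)
  truth <- list(datasets = truth_ds, candidates = world$candidates,
                overdue_accessions =
                  sort(truth_ds$accession[truth_ds$private & cited]))
  structure(list(spec = spec, dir = out_dir,
                 manifest = file.path(out_dir, "manifest.csv"),
                 text_root = text_root,
                 index = file.path(out_dir, "index.csv"),
                 pages = pages_dir, truth = truth),
            class = "datawatch_fixture")
}

# All random choices for one fixture, drawn from the current RNG stream.
build_world <- function(spec) {
  n_d <- spec$n_datasets; n_a <- spec$n_articles
  start <- spec$date_range[1L]; end <- spec$date_range[2L]
  span <- as.integer(end - start)

  pool <- sample(10000:99999, n_d + 2L * n_a + 64L)
  used <- 0L
  take_numbers <- function(k) {
    out <- pool[used + seq_len(k)]
    used <<- used + k
    out
  }

  repository <- if (n_d > 0) {
    sample(c("GEO", "SRA"), n_d, replace = TRUE, prob = c(0.85, 0.15))
  } else character()
  accession <- paste0(ifelse(repository == "GEO", "GSE", "SRX"),
                      take_numbers(n_d))
  submission <- start + sample.int(max(1L, span - 60L), n_d,
                                   replace = TRUE) - 1L
  private <- rep(FALSE, n_d)
  if (n_d > 0) {
    n_priv <- round(spec$fraction_private * n_d)
    private[sample.int(n_d, n_priv)] <- TRUE
  }
  release <- as.Date(rep(NA, n_d), origin = "1970-01-01")
  release[!private] <- submission[!private] +
    sample(14:365, sum(!private), replace = TRUE)
  datasets <- data.frame(accession = accession, repository = repository,
                         submission_date = submission,
                         release_date = release, private = private,
                         cited_by = character(n_d),
                         stringsAsFactors = FALSE)

  reserved <- new.env(parent = emptyenv())
  for (a in accession) assign(a, TRUE, envir = reserved)
  is_reserved <- function(a) exists(a, envir = reserved, inherits = FALSE)

  corrupt <- function(acc) {
    repeat {
      digits <- strsplit(sub("^[A-Z]+", "", acc), "")[[1L]]
      prefix <- sub("[0-9]+$", "", acc)
      i <- sample.int(length(digits), 1L)
      alt <- sample(setdiff(as.character(0:9), digits[i]), 1L)
      digits[i] <- alt
      cand <- paste0(prefix, paste(digits, collapse = ""))
      if (!is_reserved(cand)) {
        assign(cand, TRUE, envir = reserved)
        return(cand)
      }
    }
  }

  articles <- data.frame(article_id = sprintf("PMC%06d", seq_len(n_a)),
                         publication_date = start +
                           if (n_a > 0) sample.int(max(1L, span), n_a,
                                                   replace = TRUE) - 1L
                           else integer(),
                         text = character(n_a), stringsAsFactors = FALSE)
  cand_rows <- list()
  typo_accessions <- character()
  spurious_accessions <- character()

  for (i in seq_len(n_a)) {
    id <- articles$article_id[i]
    pdate <- articles$publication_date[i]
    sentences <- c(sample(filler_sentences, 2L))
    eligible <- which(datasets$submission_date <= pdate - 30L)
    k <- min(sample.int(3L, 1L), length(eligible))
    cited <- if (k > 0) sample(eligible, k) else integer()
    for (j in cited) {
      tmpl <- sample(citation_templates, 1L)
      if (stats::runif(1L) < spec$typo_rate) {
        typo_acc <- corrupt(datasets$accession[j])
        typo_accessions <- c(typo_accessions, typo_acc)
        sentences <- c(sentences, sprintf(tmpl, typo_acc))
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          article_id = id, accession = typo_acc,
          repository = datasets$repository[j], label = "typo",
          stringsAsFactors = FALSE)
      } else {
        sentences <- c(sentences, sprintf(tmpl, datasets$accession[j]))
        datasets$cited_by[j] <- if (nzchar(datasets$cited_by[j])) {
          paste(datasets$cited_by[j], id, sep = ";")
        } else id
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          article_id = id, accession = datasets$accession[j],
          repository = datasets$repository[j], label = "true_citation",
          stringsAsFactors = FALSE)
      }
    }
    if (stats::runif(1L) < spec$spurious_rate) {
      repeat {
        sp <- paste0("GSE", take_numbers(1L))
        if (!is_reserved(sp)) break
      }
      assign(sp, TRUE, envir = reserved)
      spurious_accessions <- c(spurious_accessions, sp)
      sentences <- c(sentences, sprintf(spurious_template, sp))
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        article_id = id, accession = sp, repository = "GEO",
        label = "spurious", stringsAsFactors = FALSE)
    }
    sentences <- c(sentences, sample(filler_sentences, 1L))
    articles$text[i] <- paste(sentences, collapse = " ")
  }

  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(article_id = character(), accession = character(),
               repository = character(), label = character(),
               stringsAsFactors = FALSE)
  list(datasets = datasets, articles = articles, candidates = candidates,
       typo_accessions = typo_accessions,
       spurious_accessions = spurious_accessions)
}

#' @export
print.datawatch_fixture <- function(x, ...) {
  cat(sprintf("<datawatch fixture: %d article(s), %d dataset(s), %d truth-overdue, dir %s>\n",
              x$spec$n_articles, x$spec$n_datasets,
              length(x$truth$overdue_accessions), x$dir))
  invisible(x)
}

#' Score a monitoring run against fixture ground truth
#'
#' Detections are the accessions the run flags for curation: those
#' classified `overdue` (cited but still private) or `invalid` (cited but
#' unknown to the repository -- the typo mode). Each detected accession is
#' mapped to its truth label; `typo` and `spurious` detections count as
#' errors, `true_citation` detections as correct. Recall is the fraction of
#' truth-overdue datasets (private and genuinely cited) that were detected
#' as overdue.
#'
#' @param run a `datawatch_run` produced on the fixture.
#' @param truth a `datawatch_fixture` or its `truth` element.
#' @return list: `precision` (a [compute_precision()] report, or `NULL`
#'   when there are zero detections), `recall`, `detected` (accession
#'   vector), `labels` (named truth label per detection).
#' @export
score_against_truth <- function(run, truth) {
  if (inherits(truth, "datawatch_fixture")) truth <- truth$truth
  refs <- run$references
  detected <- sort(unique(refs$accession[
    refs$classification %in% c("overdue", "invalid")]))
  known <- truth$candidates$accession
  if (length(setdiff(detected, known))) {
    stop("run/truth corpus mismatch: detected accession(s) absent from ",
         "ground truth: ",
         paste(utils::head(setdiff(detected, known), 3L), collapse = ", "))
  }
  labels <- truth$candidates$label[match(detected, known)]
  names(labels) <- detected
  report <- if (length(detected) > 0) {
    compute_precision(total_candidates = length(detected),
                      errors_false_match = sum(labels == "spurious"),
                      errors_typo = sum(labels == "typo"),
                      withheld_legitimate = 0L)
  } else {
    NULL
  }
  truth_overdue <- truth$overdue_accessions
  detected_overdue <- unique(refs$accession[
    refs$classification == "overdue"])
  recall <- if (length(truth_overdue) == 0) 1 else
    length(intersect(detected_overdue, truth_overdue)) /
      length(truth_overdue)
  list(precision = report, recall = recall, detected = detected,
       labels = labels)
}
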