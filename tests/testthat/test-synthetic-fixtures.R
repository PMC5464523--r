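read_fixture_page <- function(fx, acc) {
  paste(readLines(file.path(fx$pages, paste0(acc, ".txt")), warn = FALSE),
        collapse = "\n")
}

small_spec <- function(...) {
  fixture_spec(n_articles = 15, n_datasets = 20, fraction_private = 0.4,
               typo_rate = 0, spurious_rate = 0, seed = 7, ...)
}

run_fixture <- function(fx, config = NULL) {
  if (is.null(config)) {
    config <- default_config()
  }
  run_monitor(load_corpus(fx$manifest, fx$text_root),
              load_index(fx$index),
              fixture_transport(fx$pages),
              config = config,
              run_date = as.Date("2026-01-01"))
}

test_that("fixture generation is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- fixture_spec(n_articles = 10, n_datasets = 12,
                       fraction_private = 0.5, typo_rate = 0.2,
                       spurious_rate = 0.3, seed = 7)
  generate_fixture(spec, d1)
  generate_fixture(spec, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
  # a different seed changes the world
  generate_fixture(fixture_spec(n_articles = 10, n_datasets = 12,
                                fraction_private = 0.5, typo_rate = 0.2,
                                spurious_rate = 0.3, seed = 8),
                   d2 <- withr::local_tempdir())
  expect_false(identical(readLines(file.path(d1, "manifest.csv")),
                         readLines(file.path(d2, "manifest.csv"))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); runif(1)
  generate_fixture(small_spec(), withr::local_tempdir())
  expect_identical(runif(2), before[2:3])
})

test_that("fixture spec validation rejects impossible worlds", {
  expect_error(fixture_spec(n_articles = -1), ">= 0")
  expect_error(fixture_spec(typo_rate = 1.5), "\\[0, 1\\]")
  expect_error(fixture_spec(n_datasets = 0, typo_rate = 0.1),
               "impossible")
  expect_error(fixture_spec(date_range = c("2016-01-01", "2010-01-01")),
               "ordered")
})

test_that("empty world generates an empty corpus and truth", {
  fx <- generate_fixture(fixture_spec(n_articles = 0, n_datasets = 0,
                                      typo_rate = 0, seed = 1),
                         withr::local_tempdir())
  expect_identical(nrow(load_corpus(fx$manifest, fx$text_root)), 0L)
  expect_identical(nrow(fx$truth$candidates), 0L)
  expect_identical(fx$truth$overdue_accessions, character(0))
})

test_that("ground-truth labels partition candidates and pages match declared status", {
  fx <- generate_fixture(fixture_spec(n_articles = 30, n_datasets = 25,
                                      fraction_private = 0.4,
                                      typo_rate = 0.25, spurious_rate = 0.4,
                                      seed = 21), withr::local_tempdir())
  cand <- fx$truth$candidates
  expect_true(all(cand$label %in% c("true_citation", "typo", "spurious")))
  expect_true(any(cand$label == "typo"))
  expect_true(any(cand$label == "spurious"))

  # every labelled candidate literally occurs in its article's text
  corpus <- load_corpus(fx$manifest, fx$text_root)
  for (i in seq_len(nrow(cand))) {
    txt <- corpus$text[corpus$article_id == cand$article_id[i]]
    expect_true(grepl(cand$accession[i], txt, fixed = TRUE))
  }

  # parser-generator consistency: each page parses to the declared status
  sigs <- default_signatures()
  ds <- fx$truth$datasets
  page_status <- function(acc, repo) {
    as.character(parse_status_page(
      repo, read_fixture_page(fx, acc), sigs[[repo]], acc))
  }
  for (i in seq_len(nrow(ds))) {
    expect_identical(page_status(ds$accession[i], ds$repository[i]),
                     if (ds$private[i]) "private" else "public",
                     info = ds$accession[i])
  }
  typo_accs <- cand$accession[cand$label == "typo"]
  for (a in typo_accs) expect_identical(page_status(a, "GEO"), "invalid")
  spur <- cand$accession[cand$label == "spurious"]
  for (a in spur) expect_identical(page_status(a, "GEO"), "private")
})

test_that("clean fixture round-trips with precision and recall 1", {
  fx <- generate_fixture(small_spec(), withr::local_tempdir())
  run <- run_fixture(fx)
  score <- score_against_truth(run, fx)
  expect_identical(score$precision$precision, 1)
  expect_identical(score$recall, 1)
  expect_setequal(run$overdue$accession, fx$truth$overdue_accessions)
})

test_that("typo and spurious detections count as precision errors", {
  fx <- generate_fixture(fixture_spec(n_articles = 40, n_datasets = 30,
                                      fraction_private = 0.5,
                                      typo_rate = 0.3, spurious_rate = 0.3,
                                      seed = 33), withr::local_tempdir())
  run <- run_fixture(fx)
  score <- score_against_truth(run, fx)
  pr <- score$precision
  expect_gt(pr$errors_typo, 0)
  expect_gt(pr$errors_false_match, 0)
  expect_equal(pr$precision,
               pr$correct / length(score$detected))
  expect_lt(pr$precision, 1)
  # recall over truth overdue is unaffected by the error candidates
  expect_identical(score$recall, 1)
})

test_that("the published error breakdown reproduces its headline precision", {
  # 473 flagged candidates of which 1 spurious match and 14 typos:
  # the same arithmetic score_against_truth performs, in miniature
  pr <- compute_precision(473, 1, 14, 3)
  expect_identical(format(pr), "97%")
  expect_equal(pr$precision, 0.9683, tolerance = 1e-4)
})

test_that("zero detections on a nonempty truth scores recall 0", {
  fx <- generate_fixture(small_spec(), withr::local_tempdir())
  run <- run_fixture(fx)
  # strip the run to simulate a detector that found nothing
  run$references <- run$references[0, ]
  score <- score_against_truth(run, fx)
  expect_null(score$precision)
  expect_identical(score$recall, 0)
})

test_that("corpus/truth mismatch is a hard error", {
  fx <- generate_fixture(small_spec(), withr::local_tempdir())
  run <- run_fixture(fx)
  run$references$accession <- paste0("GSE9999999")
  run$references$classification <- "overdue"
  expect_error(score_against_truth(run, fx), "mismatch")
})
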