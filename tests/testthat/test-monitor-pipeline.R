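ref_row <- function(acc = "GSE1", repo = "GEO", art = "A1") {
  data.frame(accession = acc, repository = repo, article_id = art,
             stringsAsFactors = FALSE)
}

test_that("classify_reference maps evidence to classification per contract", {
  hit <- data.frame(accession = "GSE1", release_date = as.Date("2015-01-01"))
  pr <- function(status) list(accession = "GSE1", status = status)
  d <- as.Date("2014-06-01")

  got <- classify_reference(ref_row(), hit, NULL, d)
  expect_identical(got$classification, "released")
  expect_identical(got$evidence, "index_hit")
  expect_identical(got$release_date, as.Date("2015-01-01"))

  expect_identical(classify_reference(ref_row(), NULL, pr("private"), d)[,
                     c("classification", "evidence")],
                   data.frame(classification = "overdue",
                              evidence = "probe_private"))
  expect_identical(classify_reference(ref_row(), NULL, pr("invalid"),
                                      d)$classification, "invalid")
  expect_identical(classify_reference(ref_row(), NULL, pr("public"),
                                      d)$evidence, "probe_public")
  expect_identical(classify_reference(ref_row(), NULL, pr("unknown"),
                                      d)$classification, "unknown")
  expect_error(classify_reference(ref_row(), hit, pr("private"), d),
               "contract breach")
  expect_error(classify_reference(ref_row(), NULL, NULL, d), "either")
})

make_world <- function(dir) {
  # five cited accessions: GSE10 & GSE20 in index (released);
  # GSE30 & SRX40 private (overdue); GSE50 invalid
  cp <- write_corpus(dir, list(
    A1 = "Deposited as GSE10 and GSE30 in the repository.",
    A2 = "Data under GSE20, GSE30 and SRX40; also the typo GSE50.",
    A3 = "No accessions here."),
    dates = c("2015-02-01", "2015-05-01", "2015-06-01"))
  ip <- write_index_csv(file.path(dir, "index.csv"), data.frame(
    accession = c("GSE10", "GSE20"), repository = "GEO",
    submission_date = c("2014-01-01", "2014-02-01"),
    release_date = c("2014-06-01", "2014-07-01"),
    status_hint = "public", stringsAsFactors = FALSE))
  tr <- counting_transport(memory_transport(c(
    GSE30 = private_page("GSE30"), SRX40 = private_page("SRX40"),
    GSE50 = invalid_page("GSE50"),
    GSE10 = public_page("GSE10"), GSE20 = public_page("GSE20"))))
  list(corpus = load_corpus(cp$manifest, cp$text_root),
       index = load_index(ip), transport = tr)
}

test_that("run_monitor classifies a hand-enumerated world correctly", {
  w <- make_world(withr::local_tempdir())
  run <- run_monitor(w$corpus, w$index, w$transport,
                     run_date = as.Date("2017-02-01"))
  expect_identical(sort(unique(run$overdue$accession)),
                   c("GSE30", "SRX40"))
  expect_identical(unname(as.vector(run$counts)),
                   c(2L, 3L, 1L, 0L))  # released, overdue, invalid, unknown
  # partition invariant
  expect_identical(as.integer(sum(run$counts)), nrow(run$references))
  # index short-circuit: only GSE30, SRX40, GSE50 probed, each once
  expect_identical(run$n_transport_calls, 3L)
  expect_identical(transport_calls(w$transport), 3L)
  # overdue list sorted by accession with the required columns
  expect_identical(names(run$overdue),
                   c("accession", "repository", "article_id",
                     "article_publication_date", "evidence"))
  expect_identical(run$overdue$accession, sort(run$overdue$accession))
})

test_that("corpus citing only index-known accessions makes zero transport calls", {
  d <- withr::local_tempdir()
  cp <- write_corpus(d, list(A1 = "Only GSE10 and GSE20 cited."),
                     dates = "2015-01-01")
  ip <- write_index_csv(file.path(d, "index.csv"), data.frame(
    accession = c("GSE10", "GSE20"), repository = "GEO",
    submission_date = "2014-01-01", release_date = "2014-06-01",
    status_hint = "public", stringsAsFactors = FALSE))
  tr <- counting_transport(memory_transport(c()))
  run <- run_monitor(load_corpus(cp$manifest, cp$text_root),
                     load_index(ip), tr)
  expect_identical(run$n_transport_calls, 0L)
  expect_identical(unique(run$references$classification), "released")
})

test_that("empty corpus yields an empty result", {
  d <- withr::local_tempdir()
  cp <- write_corpus(d, setNames(list(), character()), character())
  ip <- write_index_csv(file.path(d, "index.csv"),
                        data.frame(accession = character(),
                                   repository = character(),
                                   submission_date = character(),
                                   release_date = character(),
                                   status_hint = character()))
  run <- run_monitor(load_corpus(cp$manifest, cp$text_root),
                     load_index(ip), memory_transport(c()))
  expect_identical(nrow(run$references), 0L)
  expect_identical(nrow(run$overdue), 0L)
})

test_that("articles dated after the run date are excluded with a warning", {
  d <- withr::local_tempdir()
  cp <- write_corpus(d, list(A1 = "GSE30 cited.", A2 = "GSE30 again."),
                     dates = c("2015-01-01", "2030-01-01"))
  tr <- memory_transport(c(GSE30 = private_page("GSE30")))
  expect_warning(
    run <- run_monitor(load_corpus(cp$manifest, cp$text_root), NULL, tr,
                       run_date = as.Date("2017-01-01")),
    "A2")
  expect_identical(run$references$article_id, "A1")
  expect_identical(run$excluded_articles, 1L)
})

test_that("runs persist to an append-only store and diff across runs", {
  d <- withr::local_tempdir()
  w <- make_world(file.path(d, "world"))
  store <- file.path(d, "store")
  run1 <- run_monitor(w$corpus, w$index, w$transport)
  p1 <- write_run(run1, store, run_id = "run-001")
  expect_error(write_run(run1, store, run_id = "run-001"), "append-only")

  back <- read_run(p1)
  expect_identical(back$references$classification,
                   run1$references$classification)
  expect_identical(back$overdue$accession, run1$overdue$accession)

  # second run: GSE30 has been released in the meantime
  tr2 <- memory_transport(c(GSE30 = public_page("GSE30"),
                            SRX40 = private_page("SRX40"),
                            GSE50 = invalid_page("GSE50")))
  run2 <- run_monitor(w$corpus, w$index, tr2)
  dd <- diff_runs(run1, run2)
  expect_identical(dd$newly_released, "GSE30")
  expect_identical(dd$still_overdue, "SRX40")
  expect_identical(dd$newly_overdue, character(0))

  # identical runs: empty diffs except still_overdue
  same <- diff_runs(run1, run1)
  expect_identical(same$newly_overdue, character(0))
  expect_identical(same$newly_released, character(0))
  expect_identical(same$still_overdue, c("GSE30", "SRX40"))
})
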