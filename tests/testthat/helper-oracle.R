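# Independent brute-force scanner: enumerate every bounded-length substring,
# keep those that are exactly prefix + digit run within [digit_min, digit_max]
# and whose neighbouring characters are not alphanumeric. Used as the oracle
# for extract_candidates(); shares no code with the package's regex path.
oracle_scan <- function(text, specs = default_patterns()) {
  out <- list()
  n <- nchar(text)
  chars <- if (n > 0) strsplit(text, "", useBytes = FALSE)[[1L]] else character()
  is_alnum <- function(ch) grepl("^[A-Za-z0-9]$", ch)
  for (spec in specs) {
    plen <- nchar(spec$prefix)
    for (start in seq_len(max(0L, n))) {
      for (dlen in spec$digit_min:spec$digit_max) {
        end <- start + plen + dlen - 1L
        if (end > n) break
        tok <- substr(text, start, end)
        if (!grepl(sprintf("^%s[0-9]{%d}$", spec$prefix, dlen), tok)) next
        before_ok <- start == 1L || !is_alnum(chars[start - 1L])
        after_ok <- end == n || !is_alnum(chars[end + 1L])
        if (before_ok && after_ok) {
          out[[length(out) + 1L]] <- data.frame(
            accession = tok, repository = spec$repository,
            start = start - 1L, end = end, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(accession = character(), repository = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$repository), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_text <- function(len) {
  alphabet <- c(LETTERS, 0:9, " ", ".", ",", "(", ")", "-", "/", ";")
  paste(sample(alphabet, len, replace = TRUE,
               prob = c(rep(2, 26), rep(2, 10), 20, rep(1, 7))),
        collapse = "")
}

as_article <- function(id, text, date = "2016-01-01") {
  list(article_id = id, text = text,
       publication_date = as.Date(date))
}

# minimal corpus on disk: articles is a named list id -> text
write_corpus <- function(dir, articles, dates) {
  dir.create(file.path(dir, "texts"), recursive = TRUE,
             showWarnings = FALSE)
  ids <- as.character(names(articles))
  for (id in ids) {
    writeLines(articles[[id]], file.path(dir, "texts", paste0(id, ".txt")))
  }
  man <- data.frame(article_id = ids,
                    publication_date = as.character(dates),
                    text_path = if (length(ids)) paste0(ids, ".txt")
                                else character())
  mp <- file.path(dir, "manifest.csv")
  write.csv(man, mp, row.names = FALSE)
  list(manifest = mp, text_root = file.path(dir, "texts"))
}

write_index_csv <- function(path, rows) {
  cols <- c("accession", "repository", "submission_date", "release_date",
            "status_hint")
  if (nrow(rows) == 0) {
    writeLines(paste(cols, collapse = ","), path)
  } else {
    write.csv(rows[, cols], path, row.names = FALSE)
  }
  path
}

# transport serving an in-memory named vector accession -> page text
memory_transport <- function(pages) {
  function(url) {
    acc <- sub(".*(acc=|term=)", "", url)
    if (!acc %in% names(pages)) stop("no page for ", acc)
    pages[[acc]]
  }
}

private_page <- function(acc) {
  sprintf("<html>Accession %s is currently private.</html>", acc)
}
public_page <- function(acc) {
  sprintf("<html>Series %s record, samples below.</html>", acc)
}
invalid_page <- function(acc) {
  sprintf("<html>Could not find a public or private accession \"%s\".</html>", acc)
}
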