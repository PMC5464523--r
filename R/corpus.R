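#' Load an article corpus from a manifest-plus-files layout
#'
#' The corpus is a flat directory of UTF-8 plain-text files -- one article
#' each -- described by a CSV manifest with header
#' `article_id,publication_date,text_path`. Publication dates are ISO-8601
#' prefixes at day, month, or year precision (see [parse_partial_date()]).
#' Article text is treated as opaque character data: no sentence or section
#' segmentation is attempted, because downstream extraction scans raw text
#' with regular expressions.
#'
#' @param manifest_path path to the manifest CSV.
#' @param text_root directory against which each `text_path` is resolved.
#' @return a data frame of class `datawatch_corpus` with columns
#'   `article_id`, `publication_date` (`Date`), `text`, `source_path`, in
#'   manifest order. Rows whose text file is missing are skipped and
#'   collected in the `skipped` attribute (a data frame with `row`,
#'   `article_id`, `reason`); a warning summarises them.
#'
#' Hard errors: a duplicate `article_id`, or an unparseable date (the error
#' names the offending manifest row).
#' @export
load_corpus <- function(manifest_path, text_root) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  man <- utils::read.csv(manifest_path, colClasses = "character",
                         fileEncoding = "UTF-8")
  need <- c("article_id", "publication_date", "text_path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(man$article_id)) {
    dup <- unique(man$article_id[duplicated(man$article_id)])
    stop("duplicate article_id in manifest: ", paste(dup, collapse = ", "))
  }
  dates <- parse_partial_date(man$publication_date)
  if (anyNA(dates) && nrow(man) > 0) {
    bad <- which(is.na(dates))[1L]
    stop(sprintf("manifest row %d (%s): unparseable publication_date '%s'",
                 bad, man$article_id[bad], man$publication_date[bad]))
  }

  n <- nrow(man)
  text <- character(n)
  keep <- logical(n)
  skipped <- list()
  for (i in seq_len(n)) {
    fp <- file.path(text_root, man$text_path[i])
    if (!file.exists(fp)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        row = i, article_id = man$article_id[i],
        reason = paste0("missing text file: ", fp),
        stringsAsFactors = FALSE)
      next
    }
    text[i] <- read_text_file(fp)
    keep[i] <- TRUE
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(row = integer(), article_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  if (nrow(skipped) > 0) {
    warning(sprintf("%d manifest row(s) skipped (missing text files): %s",
                    nrow(skipped), paste(skipped$article_id, collapse = ", ")))
  }

  out <- data.frame(
    article_id = man$article_id[keep],
    publication_date = dates[keep],
    text = text[keep],
    source_path = file.path(text_root, man$text_path[keep]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, skipped = skipped,
            class = c("datawatch_corpus", "data.frame"))
}

read_text_file <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n == 0) return("")
  txt <- readChar(path, n, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  txt
}

#' @export
print.datawatch_corpus <- function(x, ...) {
  cat(sprintf("<datawatch corpus: %d article(s), %d skipped row(s)>\n",
              nrow(x), nrow(attr(x, "skipped"))))
  if (nrow(x)) {
    cat(sprintf("  dates %s .. %s\n",
                min(x$publication_date), max(x$publication_date)))
  }
  invisible(x)
}
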