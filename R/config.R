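#' Default run configuration
#'
#' Everything tunable about a monitoring run in one list: the accession
#' pattern specs (GEO/GSE and SRA/SRX by default), the per-repository
#' signature sets, the live-transport rate limit (seconds between
#' requests), the probe-cache TTL (seconds), the extraction context-window
#' width (characters per side), and the case-sensitivity flag.
#'
#' @return a `datawatch_config` list.
#' @seealso [load_config()]
#' @export
default_config <- function() {
  structure(list(patterns = default_patterns(),
                 signatures = default_signatures(),
                 rate_limit = 0.4,
                 cache_ttl = 86400,
                 context_width = 60L,
                 case_insensitive = FALSE),
            class = "datawatch_config")
}

#' Load a run configuration from a YAML file
#'
#' Values in the file override the defaults; omitted keys keep them.
#' Layout:
#' ```yaml
#' patterns:
#'   - {repository: GEO, prefix: GSE, digit_min: 1, digit_max: 8}
#' signatures:
#'   GEO:
#'     invalid: ["Could not find a public or private accession"]
#'     private: ["is currently private"]
#' rate_limit: 0.4
#' cache_ttl: 86400
#' context_width: 60
#' case_insensitive: false
#' ```
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a `datawatch_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$patterns)) {
    cfg$patterns <- lapply(raw$patterns, function(p) {
      accession_pattern(p$repository, p$prefix,
                        digit_min = p$digit_min %||% 1L,
                        digit_max = p$digit_max %||% 8L)
    })
  }
  if (!is.null(raw$signatures)) {
    cfg$signatures <- lapply(names(raw$signatures), function(repo) {
      s <- raw$signatures[[repo]]
      signature_set(repo,
                    invalid_signatures = unlist(s$invalid),
                    private_signatures = unlist(s$private))
    })
    names(cfg$signatures) <- names(raw$signatures)
  }
  for (k in c("rate_limit", "cache_ttl", "context_width")) {
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  }
  if (!is.null(raw$case_insensitive)) {
    cfg$case_insensitive <- isTRUE(raw$case_insensitive)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
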