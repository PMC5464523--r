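---
title: "Monitoring overdue release of cited datasets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring overdue release of cited datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datawatch)
```

## The problem

Genomics repositories such as NCBI GEO and SRA operate a
hold-until-published policy: a submitted dataset stays private until the
authors' manuscript appears, at which point the authors are supposed to ask
for release. Authors forget, and enforcement is manual, so a growing pool
of datasets is *overdue*: cited by an accession number in a published
article, yet still private at the repository. `datawatch` automates the
audit: it mines article full text for accession numbers, decides for each
cited accession whether the dataset is public, and reports the backlog.

## The procedure and its assumptions

A monitoring run is a four-stage pipeline:

1. **Extraction.** Article text is scanned with per-repository regular
   expressions -- a literal uppercase prefix followed by a bounded digit
   run (`GSE` for GEO series, `SRX` for SRA experiments). Matches are
   token-bounded: a hit is rejected when the character before the prefix or
   after the digit run is alphanumeric, so `XGSE123` and `GSE456ABC` yield
   nothing. A bare `GSE[0-9]+` would fire inside longer identifiers;
   token bounding is this package's own tightening, and the brute-force
   oracle in the test suite enforces exactly the same rule independently.
   Extraction is purely lexical: it cannot reject an accession-shaped
   string used as something else (a soil-sample code, say). The ±60
   character context window exists so a curator can triage such hits.
2. **Index short circuit.** Each unique accession is first looked up in a
   local release-index snapshot (a GEOmetadb-style SQLite file or a plain
   CSV). Presence in the snapshot implies the dataset is public, so index
   hits are classified `released` with zero network traffic. The index is
   a cache of past truth; only misses go to the repository.
3. **Probe.** Misses are resolved by fetching the repository's
   accession-status page through a pluggable transport and searching the
   raw body for literal signature phrases, with total precedence
   *invalid > private > public > unknown*. A page is `public` only if the
   queried accession itself appears in it; a page with neither signature
   nor the accession is `unknown`, never `public` -- the fail-safe against
   calling an outage page "released". Transport failures degrade to
   `unknown` instead of aborting the run.
4. **Classification.** Each (article, accession) reference maps to
   `released`, `overdue` (cited but still private -- the quantity of
   interest), `invalid`, or `unknown`, and the four classes partition the
   references exactly. Overdue is evaluated at run time: any private
   dataset cited by an article published on or before the run date counts.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `digit_max` | 8 | digits | caps pathological digit runs; real GEO/SRA ids are shorter |
| `context_width` | 60 | chars/side | wide enough to judge a spurious hit by eye |
| `rate_limit` | 0.4 | s between live calls | politeness floor for the real endpoint; never applied to fixture transports |
| `cache_ttl` | 86400 | s | status changes on the release timescale, not minutes |
| `case_insensitive` | off | -- | accession prefixes are printed uppercase; the flag exists for noisy OCR corpora |

Signature phrases and pattern specs live in the run configuration
(`load_config()`), not in code.

## Analytics

* `overdue_time_series()` -- on a monthly grid, the number of datasets
  whose earliest citation is on or before `t` and whose release date is
  absent or after `t`. Releasing a dataset can only lower the curve
  (monotone response; property-tested).
* `delay_statistics()` -- submission-to-release delay in whole days,
  averaged per release year. Month-precision dates pin to the first of
  the month, so March 2005 → November 2016 is 4,263 days and, by the
  anniversary convention (`whole_years_elapsed()`), an 11-year wait.
  Records violating `release >= submission` are excluded with a warning
  and counted, never silently dropped. The statistic describes whatever
  record set it is given (all snapshot records, or only cited ones).
* `compute_precision()` -- of the flagged candidates, non-citation string
  matches and author-typo citations count as errors; legitimately withheld
  datasets (incomplete submission, privacy) are genuine citations and
  count as correct. Under that convention the worked example
  `compute_precision(473, 1, 14, 3)` renders `"97%"`; counting withheld
  datasets as errors would give 96%, which is why the convention is fixed
  here.

## The synthetic world

`generate_fixture()` emulates the corpus, the snapshot, and the status
pages with known ground truth, from a single RNG stream keyed by `seed`
(byte-identical reruns). Its defaults are one stated world, chosen once:

* 85% GEO / 15% SRA datasets (the observed detection mix is roughly that
  ratio); submissions uniform over 2010–2016, the era in which overdue
  citations were observed; public datasets release 14–365 days after
  submission, uniformly.
* each article cites 1–3 datasets already submitted at publication time;
* `typo_rate = 0.03`: a citation embeds a one-digit-corrupted accession
  that exists nowhere -- its status page carries the invalid signature;
* `spurious_rate = 0.002`: an article embeds an accession-shaped token in
  a non-dataset sentence; the token corresponds to a real but private
  repository entry, reproducing the one observed false-positive mode
  (a private accession string used as a soil-sample name).

`score_against_truth()` defines *detections* as the accessions a run
classifies `overdue` or `invalid` -- the list a curator would be handed.
Typo and spurious detections are errors; recall is measured against the
truth-overdue set (private and genuinely cited). On a clean world
(`typo_rate = spurious_rate = 0`) the pipeline must score precision 1.0
and recall 1.0, and the acceptance suite checks exactly that at
200 articles × 300 datasets.

What a green test does **not** establish: real article prose (the
generator uses template sentences with clean token boundaries, so corpus
recall on messy typography is untested), realistic publication-delay
distributions (uniform draws only), accession ranges ("GSE100–GSE105"),
and the completeness of the real signature-phrase sets ("strings such
as..." implies the live set may be larger than the two defaults).

## Numerical and design choices

* **Dates** are `Date`s pinned to the first of the month/year when given
  at month/year precision; all comparisons are calendar-exact, no
  timezones involved.
* **Boundary rule tie-break**: the specification of record for token
  boundaries is the frozen oracle example (`GSE456ABC` matches nothing);
  digit runs longer than `digit_max` therefore match nothing at all
  rather than a truncated prefix.
* **Deduplication** keys on (article, repository, accession), keeping the
  earliest mention; each unique accession is probed at most once per run,
  before classification fan-out.
* **Stale index**: an index hit is never probed, so an index/probe
  conflict cannot arise inside a run; the index claims only "was public
  when snapshotted", which is monotone in the right direction.
* **Zero-candidate inputs** (empty text, empty manifest, empty world) are
  values, not errors, everywhere downstream of loading.
* **Percent rendering** rounds to the nearest integer percent
  (458/473 → 97%).

## Known limitations

* Only accession grammars of the prefix-plus-digits form are supported;
  other repositories need only a pattern, a URL template, and a signature
  set (the registry is extensible by configuration).
* No typo correction: a mis-cited accession is reported as `invalid`,
  which is the honest lexical truth and what a curator needs to chase the
  author.
* The live transport is deliberately minimal (no retries beyond the fixed
  contract, no E-utilities bulk access); production crawling at scale is
  out of scope.
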