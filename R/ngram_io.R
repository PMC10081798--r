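#' Parse an Ngram Viewer JSON export into a frequency panel
#'
#' The Ngram Viewer returns a JSON array of `{ngram, timeseries, ...}`
#' objects, one per query term, where `timeseries` holds the yearly fraction
#' of all corpus tokens.  The Viewer divides a word's yearly appearances by
#' the total number of words in the corpus that year; this parser converts
#' those fractions to percent (x100).  `_INF` parent entries and `(All)`
#' aggregates are kept as distinct rows from plain forms — the `ngram` string
#' is used verbatim.
#'
#' @param payload a file path, a JSON string, or an already-parsed list of
#'   entries, each with fields `ngram` and `timeseries`.
#' @param year_start,year_end inclusive year range the query covered; each
#'   `timeseries` must have exactly `year_end - year_start + 1` points.
#' @param language corpus label to stamp on the panel.
#' @return A [freq_panel()] in percent units.
#' @export
parse_viewer_json <- function(payload, year_start, year_end,
                              language = "unknown") {
  if (is.character(payload) && length(payload) == 1L) {
    payload <- jsonlite::fromJSON(payload, simplifyVector = FALSE)
  }
  stopifnot(is.list(payload))
  years <- seq.int(year_start, year_end)
  n <- length(years)
  if (length(payload) == 0L) {
    warning("empty Viewer payload: returning empty panel fragment")
    values <- matrix(numeric(0), 0L, n,
                     dimnames = list(character(0), years))
    return(freq_panel(values, language, years))
  }
  rows <- lapply(payload, function(entry) {
    if (is.null(entry$ngram) || is.null(entry$timeseries)) {
      stop("Viewer entry missing 'ngram' or 'timeseries'")
    }
    ts <- as.numeric(unlist(entry$timeseries))
    if (length(ts) != n) {
      stop(sprintf(
        "timeseries for '%s' has %d points but the %d-%d range needs %d",
        entry$ngram, length(ts), year_start, year_end, n))
    }
    if (anyNA(ts) || any(ts < 0)) {
      stop(sprintf("negative or missing frequency for '%s'", entry$ngram))
    }
    ts * 100  # Viewer fraction of corpus -> percent
  })
  values <- do.call(rbind, rows)
  rownames(values) <- vapply(payload, function(e) as.character(e$ngram), "")
  freq_panel(values, language, years)
}

#' Read a totalcounts file
#'
#' Per-year corpus totals in CSV form with columns
#' `year,match_count,page_count,volume_count`.  `match_count` is the
#' denominator of the relative frequency; page and volume counts are retained
#' but unused.
#'
#' @param path CSV path.
#' @return Data frame with those columns, one row per year.
#' @export
read_total_counts <- function(path) {
  tc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "match_count")
  if (!all(need %in% names(tc))) {
    stop("totalcounts file must have columns year,match_count[,page_count,volume_count]")
  }
  if (anyDuplicated(tc$year)) stop("duplicate years in totalcounts")
  tc
}

#' Build a frequency panel from raw ngram records
#'
#' Consumes the published raw-file record format
#' `ngram TAB year TAB match_count TAB volume_count` together with the
#' corpus totals, computing
#' `frequency(word, year) = 100 * match_count / total_tokens(year)`.
#' Years with no record for a word become 0 with `observed = FALSE`; only
#' the requested words are retained.
#'
#' @param x a file path or a character vector of raw records.
#' @param totals a data frame from [read_total_counts()], covering the
#'   full year range with positive `match_count`.
#' @param year_start,year_end inclusive year range of the output panel.
#' @param words words to retain (verbatim match).
#' @param language corpus label to stamp on the panel.
#' @return A [freq_panel()] in percent units.
#' @export
parse_raw_ngram <- function(x, totals, year_start, year_end, words,
                            language = "unknown") {
  if (length(x) == 1L && file.exists(x)) x <- readLines(x, encoding = "UTF-8")
  years <- seq.int(year_start, year_end)
  tot <- totals$match_count[match(years, totals$year)]
  if (anyNA(tot)) {
    stop("totalcounts do not cover years: ",
         paste(years[is.na(tot)], collapse = ", "))
  }
  if (any(tot <= 0)) {
    stop("non-positive total token count for years: ",
         paste(years[tot <= 0], collapse = ", "))
  }
  fields <- strsplit(x, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 4L & nzchar(x))
  if (length(bad)) {
    stop("malformed raw ngram record (expected 4 tab-separated fields) at line ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  keep <- which(nf == 4L)
  rec_word <- vapply(fields[keep], `[[`, "", 1L)
  rec_year <- suppressWarnings(as.integer(vapply(fields[keep], `[[`, "", 2L)))
  rec_count <- suppressWarnings(as.numeric(vapply(fields[keep], `[[`, "", 3L)))
  if (anyNA(rec_year) || anyNA(rec_count) || any(rec_count != floor(rec_count))) {
    i <- which(is.na(rec_year) | is.na(rec_count) |
                 rec_count != floor(rec_count))[1L]
    stop("malformed raw ngram record (non-integer year or count) at line ",
         keep[i])
  }
  values <- matrix(0, length(words), length(years),
                   dimnames = list(words, years))
  observed <- matrix(FALSE, length(words), length(years),
                     dimnames = list(words, years))
  sel <- rec_word %in% words & rec_year >= year_start & rec_year <= year_end
  if (any(sel)) {
    idx <- cbind(rec_word[sel], as.character(rec_year[sel]))
    values[idx] <- 100 * rec_count[sel] / tot[match(rec_year[sel], years)]
    observed[idx] <- TRUE
  }
  unseen <- words[rowSums(observed) == 0L]
  if (length(unseen)) {
    message("words with no records in range (all-zero series): ",
            paste(unseen, collapse = ", "))
  }
  freq_panel(values, language, years, observed)
}

viewer_cache_file <- function(cache_dir, word, corpus, year_start, year_end,
                              smoothing) {
  safe <- utils::URLencode(word, reserved = TRUE)
  file.path(cache_dir, sprintf("%s_%s_%d-%d_s%d.json",
                               corpus, safe, year_start, year_end, smoothing))
}

#' Fetch a frequency panel from the Ngram Viewer, cache-first
#'
#' Looks each word up in `cache_dir` first; only missing words trigger a
#' network request, and every fetched response is persisted verbatim to the
#' cache before parsing, so a complete cache makes the call a pure function
#' of its arguments.  Smoothing defaults to 0 (raw yearly values): the
#' downstream correlations are computed on yearly values, and smoothing would
#' leak autocorrelation into them.
#'
#' @param words query terms (plain words or `_INF` expansions).
#' @param corpus corpus label in the 2019-release naming, e.g. `"en-GB-2019"`.
#' @param year_start,year_end inclusive year range.
#' @param cache_dir directory holding one JSON payload per query.
#' @param smoothing Viewer smoothing parameter; default 0.
#' @param offline when `TRUE`, never touch the network; error if the cache is
#'   incomplete.
#' @param max_retries retries per word on transient failure.
#' @return A [freq_panel()] in percent units covering all returned series.
#' @export
fetch_panel <- function(words, corpus, year_start, year_end, cache_dir,
                        smoothing = 0, offline = FALSE, max_retries = 3L) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(words, viewer_cache_file, "", cache_dir = cache_dir,
                  corpus = corpus, year_start = year_start,
                  year_end = year_end, smoothing = smoothing)
  missing <- words[!file.exists(paths)]
  if (length(missing) && offline) {
    stop("offline and cache incomplete; missing words: ",
         paste(missing, collapse = ", "))
  }
  for (w in missing) {
    url <- paste0(
      "https://books.google.com/ngrams/json?content=",
      utils::URLencode(w, reserved = TRUE),
      "&year_start=", year_start, "&year_end=", year_end,
      "&corpus=", utils::URLencode(corpus, reserved = TRUE),
      "&smoothing=", smoothing)
    dest <- viewer_cache_file(cache_dir, w, corpus, year_start, year_end,
                              smoothing)
    ok <- FALSE
    for (k in seq_len(max_retries)) {
      ok <- tryCatch({
        utils::download.file(url, dest, quiet = TRUE, mode = "wb")
        TRUE
      }, error = function(e) FALSE, warning = function(w) FALSE)
      if (ok) break
      Sys.sleep(2^k)  # backoff before retrying (rate limits)
    }
    if (!ok && file.exists(dest)) unlink(dest)
  }
  still <- words[!file.exists(paths)]
  if (length(still)) {
    stop("could not fetch words (network failure with incomplete cache): ",
         paste(still, collapse = ", "))
  }
  frags <- lapply(paths, function(p) {
    parse_viewer_json(readChar(p, file.size(p), useBytes = TRUE),
                      year_start, year_end, language = corpus)
  })
  values <- do.call(rbind, lapply(frags, function(f) f$values))
  freq_panel(values, corpus, seq.int(year_start, year_end))
}
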