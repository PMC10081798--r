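#' Yearly word-frequency panel
#'
#' A `freq_panel` holds per-word yearly relative frequencies for one corpus
#' over a contiguous year range.  Frequencies are stored in percent of all
#' corpus tokens in that year: a word making up 1% of a year's tokens stores
#' `1.0`.  Cells with no underlying record are `0.0` with `observed = FALSE`,
#' since a word absent from a year's books genuinely has zero relative
#' frequency; the flag lets downstream reports state coverage.
#'
#' @param values numeric matrix, words in rows (rownames), years in columns.
#' @param language corpus label, e.g. `"en-GB-2019"`.
#' @param years integer vector of contiguous years matching the columns.
#' @param observed logical matrix of the same shape; `FALSE` marks cells
#'   filled as zero because no record existed.  Defaults to all `TRUE`.
#' @param unit `"percent"` for raw panels, `"ratio"` after the
#'   most-common-word adjustment.
#'
#' @return An object of class `freq_panel`.
#' @seealso [parse_viewer_json()], [parse_raw_ngram()], [generate_panel()],
#'   [common_word_adjust()]
#' @export
freq_panel <- function(values, language, years,
                       observed = NULL, unit = "percent") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (words x years)")
  }
  if (nrow(values) > 0L && is.null(rownames(values))) {
    stop("`values` must have word rownames")
  }
  years <- as.integer(years)
  if (length(years) != ncol(values)) {
    stop("length(years) must equal ncol(values)")
  }
  if (length(years) > 1L && !all(diff(years) == 1L)) {
    stop("`years` must be contiguous")
  }
  if (anyNA(values)) stop("panel values must not be NA")
  if (any(values < 0)) stop("panel frequencies must be non-negative")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate word rows: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (is.null(observed)) {
    observed <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  stopifnot(is.logical(observed), all(dim(observed) == dim(values)))
  unit <- match.arg(unit, c("percent", "ratio"))
  colnames(values) <- years
  dimnames(observed) <- dimnames(values)
  structure(
    list(language = as.character(language), years = years,
         values = values, observed = observed, unit = unit),
    class = "freq_panel"
  )
}

#' @export
print.freq_panel <- function(x, ...) {
  cat(sprintf("<freq_panel> %s: %d words x %d years (%d-%d), unit = %s\n",
              x$language, nrow(x$values), length(x$years),
              min(x$years), max(x$years), x$unit))
  miss <- sum(!x$observed)
  if (miss > 0L) cat(sprintf("  %d unobserved cells filled as 0\n", miss))
  invisible(x)
}

#' @export
dim.freq_panel <- function(x) dim(x$values)

#' Words present in a panel
#' @param panel a [freq_panel()].
#' @return Character vector of row words.
#' @export
panel_words <- function(panel) {
  stopifnot(inherits(panel, "freq_panel"))
  rownames(panel$values)
}

#' Extract one word's yearly series from a panel
#' @param panel a [freq_panel()].
#' @param word word to extract (verbatim match against row names).
#' @return Named numeric vector (names are years).
#' @export
panel_series <- function(panel, word) {
  stopifnot(inherits(panel, "freq_panel"))
  if (!word %in% rownames(panel$values)) {
    stop(sprintf("word '%s' not present in panel for %s", word,
                 panel$language))
  }
  panel$values[word, ]
}

#' Write / read a panel as long-format CSV
#'
#' Long format with columns `language,word,year,frequency_percent,observed_flag`
#' (the `frequency_percent` column carries ratio values after adjustment).
#'
#' @param panel a [freq_panel()].
#' @param path output CSV path.
#' @return `write_panel_csv` invisibly returns `path`; `read_panel_csv`
#'   returns a [freq_panel()].
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "freq_panel"))
  long <- data.frame(
    language = panel$language,
    word = rep(rownames(panel$values), times = length(panel$years)),
    year = rep(panel$years, each = nrow(panel$values)),
    frequency_percent = as.vector(panel$values),
    observed_flag = as.vector(panel$observed),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("language", "word", "year", "frequency_percent", "observed_flag")
  if (!all(need %in% names(long))) {
    stop("panel CSV must have columns: ", paste(need, collapse = ", "))
  }
  lang <- unique(long$language)
  if (length(lang) != 1L) stop("panel CSV must contain a single language")
  years <- sort(unique(long$year))
  words <- unique(long$word)
  values <- matrix(0, length(words), length(years),
                   dimnames = list(words, years))
  observed <- matrix(FALSE, length(words), length(years),
                     dimnames = list(words, years))
  values[cbind(long$word, as.character(long$year))] <- long$frequency_percent
  observed[cbind(long$word, as.character(long$year))] <- long$observed_flag
  freq_panel(values, lang, years, observed)
}
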