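#' Most-common-word adjustment
#'
#' Divides every word's yearly frequency by the frequency of the corpus's
#' most common word (in practice its most frequent noun, e.g. English
#' "time", German "Zeit") in the same year, cancelling year-wise changes in
#' corpus size and composition — the influx of data as more books are
#' digitized.  The adjustment makes the downstream composite exactly
#' invariant to any positive per-year rescaling of the whole panel.  The
#' common word itself is dropped from the output; the result is unitless.
#'
#' @param panel a [freq_panel()] in percent units.
#' @param common_word the reference word; must be present with strictly
#'   positive frequency in every year.
#' @return A [freq_panel()] with `unit = "ratio"`, without the common word.
#' @export
common_word_adjust <- function(panel, common_word) {
  stopifnot(inherits(panel, "freq_panel"))
  if (!common_word %in% rownames(panel$values)) {
    stop(sprintf("common word '%s' missing from panel for %s",
                 common_word, panel$language))
  }
  ref <- panel$values[common_word, ]
  if (any(ref <= 0)) {
    stop(sprintf("common word '%s' has zero frequency in year(s): %s",
                 common_word,
                 paste(panel$years[ref <= 0], collapse = ", ")))
  }
  keep <- rownames(panel$values) != common_word
  values <- sweep(panel$values[keep, , drop = FALSE], 2L, ref, "/")
  freq_panel(values, panel$language, panel$years,
             observed = panel$observed[keep, , drop = FALSE],
             unit = "ratio")
}

#' Z-transform a yearly series
#'
#' Centers and scales by the sample standard deviation (denominator n - 1),
#' so the output has mean 0 and sample sd 1.
#'
#' @param values numeric series of length >= 2 with positive variance.
#' @return The z-scored series.
#' @export
zscore_series <- function(values) {
  if (length(values) < 2L) stop("series must have length >= 2")
  if (anyNA(values)) stop("series must not contain NA")
  s <- stats::sd(values)
  if (s == 0) stop("constant series: standard deviation is zero")
  (values - mean(values)) / s
}

#' Composite construct series for one language
#'
#' Z-transforms every included lexicon word's adjusted series and aggregates
#' across words per year.  Aggregation defaults to the mean; mean and sum
#' differ only by the constant word count, so every downstream Pearson
#' correlation is identical under either choice — the mean keeps composite
#' scales comparable across lists of different length.
#'
#' Zero-variance words (for instance terms coined after the panel starts
#' that never appear) cannot be z-scored; by default they are dropped with a
#' warning rather than failing the run, and `n_words` records the surviving
#' count.
#'
#' @param adjusted a [freq_panel()], normally the output of
#'   [common_word_adjust()].
#' @param lexicon a `lexicon`; its included words must all be present in the
#'   panel.
#' @param aggregation `"mean"` (default) or `"sum"` across words.
#' @param zero_variance `"drop"` (default) or `"fail"`.
#' @return An object of class `composite_series` with fields `construct`,
#'   `language`, `years`, `values`, `n_words`, `n_languages`.
#' @export
composite <- function(adjusted, lexicon,
                      aggregation = c("mean", "sum"),
                      zero_variance = c("drop", "fail")) {
  stopifnot(inherits(adjusted, "freq_panel"), inherits(lexicon, "lexicon"))
  aggregation <- match.arg(aggregation)
  zero_variance <- match.arg(zero_variance)
  words <- filtered_words(lexicon)
  missing <- setdiff(words, rownames(adjusted$values))
  if (length(missing)) {
    stop(sprintf("lexicon words missing from panel for %s: %s",
                 adjusted$language, paste(missing, collapse = ", ")))
  }
  sub <- adjusted$values[words, , drop = FALSE]
  ctr <- sub - rowMeans(sub)
  sds <- sqrt(rowSums(ctr^2) / (ncol(sub) - 1L))
  flat <- sds == 0
  if (any(flat)) {
    if (zero_variance == "fail") {
      stop("zero-variance word series: ",
           paste(words[flat], collapse = ", "))
    }
    warning(sprintf("dropping %d zero-variance word(s) in %s/%s: %s",
                    sum(flat), lexicon$construct, adjusted$language,
                    paste(words[flat], collapse = ", ")))
    ctr <- ctr[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  if (nrow(ctr) == 0L) {
    stop(sprintf("no usable words left for %s/%s",
                 lexicon$construct, adjusted$language))
  }
  z <- ctr / sds
  vals <- if (aggregation == "mean") colMeans(z) else colSums(z)
  new_composite(lexicon$construct, adjusted$language, adjusted$years,
                vals, n_words = nrow(ctr), n_languages = 1L)
}

new_composite <- function(construct, language, years, values,
                          n_words, n_languages) {
  structure(
    list(construct = construct, language = language,
         years = as.integer(years), values = unname(as.numeric(values)),
         n_words = as.integer(n_words), n_languages = as.integer(n_languages)),
    class = "composite_series"
  )
}

#' @export
print.composite_series <- function(x, ...) {
  cat(sprintf(
    "<composite_series> %s / %s: %d years (%d-%d), %d words, %d language(s)\n",
    x$construct, x$language, length(x$years), min(x$years), max(x$years),
    x$n_words, x$n_languages))
  invisible(x)
}

#' Pool per-language composites into one multi-language index
#'
#' Unweighted mean over languages of the per-language composite values, year
#' by year.  All inputs must share the construct and year range.
#'
#' @param series list of `composite_series` for the same construct.
#' @param construct optional construct label to enforce.
#' @return A `composite_series` with `language = "pooled"`; `n_words` is the
#'   total surviving word count over languages.
#' @export
pool_languages <- function(series, construct = NULL) {
  stopifnot(is.list(series), length(series) >= 1L,
            all(vapply(series, inherits, TRUE, "composite_series")))
  cons <- unique(vapply(series, `[[`, "", "construct"))
  if (length(cons) != 1L) {
    stop("cannot pool mixed constructs: ", paste(cons, collapse = ", "))
  }
  if (!is.null(construct) && cons != construct) {
    stop(sprintf("expected construct '%s', got '%s'", construct, cons))
  }
  yrs <- series[[1L]]$years
  same <- vapply(series, function(s) identical(s$years, yrs), TRUE)
  if (!all(same)) stop("mismatched year ranges across languages")
  m <- vapply(series, `[[`, numeric(length(yrs)), "values")
  new_composite(cons, "pooled", yrs, rowMeans(as.matrix(m)),
                n_words = sum(vapply(series, `[[`, 1L, "n_words")),
                n_languages = length(series))
}

#' Write composite series to CSV
#'
#' Long format `construct,language,year,value,n_words`.
#'
#' @param series a `composite_series` or a list of them.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_composite_csv <- function(series, path) {
  if (inherits(series, "composite_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(construct = s$construct, language = s$language,
               year = s$years, value = s$values, n_words = s$n_words,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
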