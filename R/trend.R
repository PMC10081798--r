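#' Pearson correlation with significance stars
#'
#' Sample Pearson correlation with the two-sided p-value from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.  `r` is clamped to `[-1, 1]` against floating-point overshoot.
#' Stars follow the usual thresholds: `*` p < .05, `**` p < .01,
#' `***` p < .001.
#'
#' @param x,y numeric series of equal length `n >= 3`, each with positive
#'   variance.
#' @return An object of class `cor_result`: list with `r`, `p`, `n`, `df`,
#'   `stars` and the `pair` of labels.
#' @export
pearson_cor <- function(x, y) {
  labs <- c(deparse1(substitute(x)), deparse1(substitute(y)))
  if (length(x) != length(y)) stop("series lengths differ")
  n <- length(x)
  if (n < 3L) stop("need n >= 3 observations")
  if (anyNA(x) || anyNA(y)) stop("series must not contain NA")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input series")
  }
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  }
  structure(
    list(pair = labs, r = r, p = p, n = n, df = df, stars = p_stars(p)),
    class = "cor_result"
  )
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("r = %.3f%s (p = %.3g, n = %d) [%s ~ %s]\n",
              x$r, x$stars, x$p, x$n, x$pair[1], x$pair[2]))
  invisible(x)
}

#' Correlation matrix among construct composites, years, and a control
#'
#' Computes all pairwise Pearson correlations among the composite series,
#' the calendar-year index, and (last) the control construct, mirroring the
#' layout of a trend-correlation table: constructs first, then `Years`, then
#' the control row.  The year index enters as the calendar years themselves —
#' Pearson r is invariant to its affine coding.  Each cell carries r, the
#' two-sided p, n and stars; a Holm-corrected p is reported alongside for
#' transparency but stars stay per-cell, uncorrected.  Cells whose inputs
#' fail (for example zero variance) are recorded as `NA` rather than
#' aborting the matrix.
#'
#' @param composites named list of `composite_series` (or plain numeric
#'   series); names label the rows.
#' @param year_index numeric year series; `NULL` to omit the `Years` row.
#' @param control name of the control construct in `composites` (ordered
#'   last), or `NULL`.
#' @return An object of class `cor_matrix` holding matrices `r`, `p`, `n`,
#'   `stars`, `holm_p` over the ordered labels.
#' @export
correlation_matrix <- function(composites, year_index = NULL,
                               control = NULL) {
  stopifnot(is.list(composites), length(composites) >= 1L,
            !is.null(names(composites)))
  series <- lapply(composites, function(s) {
    if (inherits(s, "composite_series")) s$values else as.numeric(s)
  })
  lens <- lengths(series)
  if (length(unique(lens)) != 1L) {
    stop("all composite series must share the year range")
  }
  if (!is.null(control)) {
    if (!control %in% names(series)) {
      stop("control construct '", control, "' not among composites")
    }
    series <- c(series[setdiff(names(series), control)])
    ctrl_series <- composites[[control]]
    ctrl_vals <- if (inherits(ctrl_series, "composite_series")) {
      ctrl_series$values
    } else {
      as.numeric(ctrl_series)
    }
  }
  if (!is.null(year_index)) {
    if (length(year_index) != lens[1L]) {
      stop("year index length must match the composites")
    }
    series$Years <- as.numeric(year_index)
  }
  if (!is.null(control)) series[[control]] <- ctrl_vals
  labels <- names(series)
  k <- length(series)
  mk <- function(init) matrix(init, k, k, dimnames = list(labels, labels))
  r <- mk(NA_real_); p <- mk(NA_real_); n <- mk(NA_integer_)
  stars <- mk(NA_character_)
  failed <- character(0)
  for (i in seq_len(k)) {
    r[i, i] <- 1; p[i, i] <- 0; n[i, i] <- lens[1L]; stars[i, i] <- ""
    for (j in seq_len(i - 1L)) {
      res <- tryCatch(pearson_cor(series[[i]], series[[j]]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failed <- c(failed, sprintf("%s ~ %s: %s", labels[i], labels[j],
                                    conditionMessage(res)))
      } else {
        r[i, j] <- r[j, i] <- res$r
        p[i, j] <- p[j, i] <- res$p
        n[i, j] <- n[j, i] <- res$n
        stars[i, j] <- stars[j, i] <- res$stars
      }
    }
  }
  low <- lower.tri(p)
  holm <- mk(NA_real_)
  holm[low] <- stats::p.adjust(p[low], method = "holm")
  holm[upper.tri(holm)] <- t(holm)[upper.tri(holm)]
  structure(
    list(labels = labels, r = r, p = p, n = n, stars = stars,
         holm_p = holm, control = control, failed = failed),
    class = "cor_matrix"
  )
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  k <- length(x$labels)
  cells <- matrix("", k, k, dimnames = list(x$labels, x$labels))
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      cells[i, j] <- if (is.na(x$r[i, j])) "NA" else
        paste0(formatC(x$r[i, j], digits = digits, format = "f"),
               x$stars[i, j])
    }
  }
  n_show <- if (k >= 2L && !is.na(x$n[2, 1])) x$n[2, 1] else x$n[1, 1]
  cat(sprintf("Correlation matrix (n = %d)\n", n_show))
  print(as.data.frame(cells[, -k, drop = FALSE]), right = TRUE)
  cat("Note: * p < .05; ** p < .01; *** p < .001.\n")
  if (length(x$failed)) {
    cat("Failed cells:\n  ", paste(x$failed, collapse = "\n  "), "\n")
  }
  invisible(x)
}

#' Long-format view of a correlation matrix
#'
#' @param x a `cor_matrix`.
#' @param language optional label copied into a `language` column.
#' @return Data frame with one row per lower-triangular pair:
#'   `pair_a, pair_b, language, r, p, n, stars, holm_p`.
#' @export
cor_matrix_long <- function(x, language = NA_character_) {
  stopifnot(inherits(x, "cor_matrix"))
  k <- length(x$labels)
  rows <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair_a = x$labels[i], pair_b = x$labels[j], language = language,
        r = x$r[i, j], p = x$p[i, j], n = x$n[i, j],
        stars = x$stars[i, j], holm_p = x$holm_p[i, j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rolling mean of a word's yearly series
#'
#' Five consecutive years by default.  Windows are trailing (the value at
#' year `t` averages years `t - window + 1` through `t`), keeping the
#' diagnostic causal; `align = "centered"` is available for the centered
#' convention (odd windows only).  Output length is `n - window + 1`.
#'
#' @param values numeric series (raw per-word frequencies).
#' @param window window length in years, default 5.
#' @param years optional year labels parallel to `values`.
#' @param align `"trailing"` (default) or `"centered"`.
#' @param word,language,construct optional metadata carried on the result.
#' @return An object of class `rolling_series` with `years` and `values` of
#'   length `n - window + 1`.
#' @export
rolling_mean <- function(values, window = 5L, years = NULL,
                         align = c("trailing", "centered"),
                         word = NA_character_, language = NA_character_,
                         construct = NA_character_) {
  align <- match.arg(align)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  n <- length(values)
  if (n < window) stop("series shorter than the rolling window")
  if (align == "centered" && window %% 2L == 0L) {
    stop("centered alignment needs an odd window")
  }
  out <- as.numeric(zoo::rollmean(values, k = window,
                                  align = if (align == "trailing") "right"
                                          else "center"))
  if (is.null(years)) years <- seq_len(n)
  yr <- if (align == "trailing") years[seq.int(window, n)]
        else years[seq.int((window + 1L) %/% 2L, n - window %/% 2L)]
  structure(
    list(word = word, language = language, construct = construct,
         window = window, align = align,
         years = yr, values = out),
    class = "rolling_series"
  )
}

#' @export
print.rolling_series <- function(x, ...) {
  cat(sprintf("<rolling_series> %s (%s/%s): window %d (%s), %d points\n",
              x$word, x$construct, x$language, x$window, x$align,
              length(x$values)))
  invisible(x)
}

#' Qualitative trend label for a rolling-mean series
#'
#' Fits an ordinary least-squares slope of the rolling values on position
#' and classifies: `increase` if the slope exceeds `slope_epsilon`,
#' `decrease` below `-slope_epsilon`, otherwise `flat` (strict
#' inequalities).  The default epsilon is 1% of the series' value range per
#' step, so a series must move appreciably over its span to earn a label.
#'
#' @param rolling a `rolling_series` (or plain numeric vector) of length
#'   >= 2.
#' @param slope_epsilon slope threshold; `NULL` for the default.
#' @return `"increase"`, `"decrease"` or `"flat"`.
#' @export
trend_label <- function(rolling, slope_epsilon = NULL) {
  vals <- if (inherits(rolling, "rolling_series")) rolling$values
          else as.numeric(rolling)
  m <- length(vals)
  if (m < 2L) stop("need at least 2 rolling values")
  if (is.null(slope_epsilon)) {
    slope_epsilon <- 0.01 * diff(range(vals))
  }
  pos <- seq_len(m)
  slope <- stats::cov(pos, vals) / stats::var(pos)
  if (slope > slope_epsilon) "increase"
  else if (slope < -slope_epsilon) "decrease"
  else "flat"
}

#' Rolling means for every word of a panel
#'
#' @param panel a raw [freq_panel()].
#' @param window,align passed to [rolling_mean()].
#' @param construct_of optional named character vector mapping words to
#'   construct labels for the output metadata.
#' @return Data frame `word,language,construct,year,rolling_mean,trend`.
#' @export
panel_rolling_means <- function(panel, window = 5L,
                                align = c("trailing", "centered"),
                                construct_of = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  align <- match.arg(align)
  rows <- lapply(rownames(panel$values), function(w) {
    cons <- if (!is.null(construct_of) && w %in% names(construct_of)) {
      construct_of[[w]]
    } else {
      NA_character_
    }
    rm <- rolling_mean(panel$values[w, ], window = window,
                       years = panel$years, align = align,
                       word = w, language = panel$language,
                       construct = cons)
    data.frame(word = w, language = panel$language, construct = cons,
               year = rm$years, rolling_mean = rm$values,
               trend = trend_label(rm), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
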