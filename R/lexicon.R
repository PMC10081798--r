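#' Construct word lists (lexicons)
#'
#' A lexicon is the curated word list for one construct in one language.
#' Curation outcomes — translation, native-speaker double-meaning screening,
#' exclusion of synonyms with broader semantic meaning — are recorded as data
#' in the list file, never recomputed: those steps are human work and the
#' package only consumes their result.
#'
#' The file dialect is UTF-8 TSV with a header row and columns `word`,
#' `include` (true/false), `exclusion_reason` (one of `none`,
#' `double_meaning`, `untranslatable`, `broader_semantic`, `other`), `notes`
#' (free text), and optional `inflections` (comma-joined forms).  One file per
#' (construct, language); the filename convention is
#' `<construct>.<corpus-label>.tsv`.
#'
#' Words are compared case-folded for duplicate detection but kept verbatim
#' for querying: the Ngram corpora are case-sensitive (German nouns are
#' capitalized) and folding only for dedup avoids false merges.
#'
#' @param path path to a word-list TSV file.
#' @param construct construct label; inferred from the filename when `NULL`.
#' @param language corpus label; inferred from the filename when `NULL`.
#' @return An object of class `lexicon` with fields `construct`, `language`
#'   and `entries` (a data frame).
#' @export
read_lexicon <- function(path, construct = NULL, language = NULL) {
  if (!file.exists(path)) stop("word-list file not found: ", path)
  base <- sub("\\.tsv$", "", basename(path))
  parts <- strsplit(base, ".", fixed = TRUE)[[1]]
  if (is.null(construct)) {
    construct <- if (length(parts) >= 2L) parts[[1]] else base
  }
  if (is.null(language)) {
    language <- if (length(parts) >= 2L) {
      paste(parts[-1], collapse = ".")
    } else {
      "unknown"
    }
  }
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           colClasses = "character", fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no entries in word-list file: ", path)
  need <- c("word", "include", "exclusion_reason")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("word-list file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(tab$notes)) tab$notes <- ""
  if (is.null(tab$inflections)) tab$inflections <- ""

  problems <- character(0)
  # header is line 1, row i is line i + 1
  line_of <- function(i) i + 1L
  reasons <- c("none", "double_meaning", "untranslatable",
               "broader_semantic", "other")
  inc <- rep(NA, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    w <- tab$word[i]
    if (!nzchar(w) || grepl("\\s", w)) {
      problems <- c(problems, sprintf(
        "line %d: word must be a single non-empty token (got '%s')",
        line_of(i), w))
    }
    iv <- tolower(tab$include[i])
    if (!iv %in% c("true", "false")) {
      problems <- c(problems, sprintf(
        "line %d: include must be true/false (got '%s')",
        line_of(i), tab$include[i]))
    } else {
      inc[i] <- iv == "true"
    }
    if (!tab$exclusion_reason[i] %in% reasons) {
      problems <- c(problems, sprintf(
        "line %d: unknown exclusion_reason '%s'",
        line_of(i), tab$exclusion_reason[i]))
    }
    if (identical(inc[i], TRUE) && tab$exclusion_reason[i] != "none") {
      problems <- c(problems, sprintf(
        "line %d: include=true requires exclusion_reason=none", line_of(i)))
    }
    if (identical(inc[i], FALSE) && tab$exclusion_reason[i] == "none") {
      problems <- c(problems, sprintf(
        "line %d: excluded word must state an exclusion_reason", line_of(i)))
    }
  }
  folded <- casefold(tab$word)
  dup <- duplicated(folded)
  if (any(dup)) {
    for (i in which(dup)) {
      problems <- c(problems, sprintf(
        "line %d: duplicate word '%s' (case-folded)", line_of(i), tab$word[i]))
    }
  }
  if (length(problems)) {
    stop("invalid word-list file ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }
  entries <- data.frame(
    word = tab$word, include = inc,
    exclusion_reason = tab$exclusion_reason,
    notes = tab$notes, inflections = tab$inflections,
    stringsAsFactors = FALSE
  )
  lex <- new_lexicon(construct, language, entries)
  if (!any(entries$include)) {
    warning(sprintf("lexicon %s/%s has no included words and is unusable",
                    construct, language))
  }
  lex
}

#' Construct a lexicon from an entries data frame
#'
#' @param construct construct label (e.g. `anxiety`, `digitalization`,
#'   `religion`).
#' @param language corpus label.
#' @param entries data frame with columns `word`, `include`,
#'   `exclusion_reason`, and optionally `notes` and `inflections`.
#' @return A `lexicon` object.
#' @export
new_lexicon <- function(construct, language, entries) {
  stopifnot(is.data.frame(entries),
            all(c("word", "include", "exclusion_reason") %in% names(entries)))
  if (is.null(entries$notes)) entries$notes <- ""
  if (is.null(entries$inflections)) entries$inflections <- ""
  if (anyDuplicated(casefold(entries$word))) {
    stop("duplicate words (case-folded) in lexicon")
  }
  structure(
    list(construct = as.character(construct),
         language = as.character(language),
         entries = entries),
    class = "lexicon"
  )
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %s / %s: %d entries (%d included)\n",
              x$construct, x$language, nrow(x$entries),
              sum(x$entries$include)))
  invisible(x)
}

#' Included words of a lexicon
#'
#' Returns exactly the words flagged `include = true`, in file order.
#'
#' @param lex a `lexicon`.
#' @return Character vector of included words.
#' @export
filtered_words <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  w <- lex$entries$word[lex$entries$include]
  if (length(w) == 0L) {
    stop(sprintf("lexicon %s/%s has no included words",
                 lex$construct, lex$language))
  }
  w
}

#' Inflection-expanded query terms
#'
#' Suffixes every included word with the literal `_INF` tag, the Ngram Viewer
#' syntax that expands a query to all inflected forms of the word.  Used for
#' the dominance consistency check: the curated base form should be the most
#' frequent of its inflections.
#'
#' @param lex a `lexicon`.
#' @return Character vector of `<word>_INF` query strings, parallel to
#'   [filtered_words()].
#' @export
inflection_terms <- function(lex) {
  paste0(filtered_words(lex), "_INF")
}

#' Dominance check over a word's inflections
#'
#' Given a panel restricted to the inflected forms of one base word, find the
#' form with the largest summed frequency over the year range and report
#' whether it is the base word itself (case-folded comparison).  Ties are
#' broken by lexicographic order of the form, so the result is deterministic
#' and invariant to the order the series are supplied in.
#'
#' @param word the lexicon's base word.
#' @param inflection_panel a [freq_panel()] whose rows are the inflected
#'   forms of `word`.
#' @return List with `dominant_form`, `is_base_dominant`, and the named
#'   vector of per-form `sums`.
#' @export
dominance_check <- function(word, inflection_panel) {
  stopifnot(inherits(inflection_panel, "freq_panel"))
  if (nrow(inflection_panel$values) == 0L) {
    stop("empty inflection panel for word '", word, "'")
  }
  sums <- rowSums(inflection_panel$values)
  # lexicographic tie-break: sort names first, then take the first argmax
  ord <- order(names(sums), method = "radix")
  sums <- sums[ord]
  dominant <- names(sums)[which.max(sums)]
  list(dominant_form = dominant,
       is_base_dominant = casefold(dominant) == casefold(word),
       sums = sums)
}

#' Write a lexicon back to the TSV dialect
#' @param lex a `lexicon`.
#' @param path output path; defaults to the `<construct>.<language>.tsv`
#'   convention in the current directory.
#' @return Invisibly, `path`.
#' @export
write_lexicon <- function(lex, path = NULL) {
  stopifnot(inherits(lex, "lexicon"))
  if (is.null(path)) path <- sprintf("%s.%s.tsv", lex$construct, lex$language)
  out <- lex$entries
  out$include <- ifelse(out$include, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
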