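#' Default most-common-word map
#'
#' The most frequent noun per corpus used as the influx-adjustment
#' reference.  Defaults follow the 2019-release corpora: English "time",
#' German "Zeit", Spanish "parte", Russian "эго", French
#' "temps", Italian "parte"; the synthetic generator names its reference row
#' `the_common_word`.  Each entry is overridable per run.
#'
#' @return Named character vector, corpus label to word.
#' @export
default_common_words <- function() {
  c("en-GB-2019" = "time", "de-2019" = "Zeit", "es-2019" = "parte",
    "ru-2019" = "эго", "fr-2019" = "temps",
    "it-2019" = "parte", "en-fiction-2019" = "time")
}

#' Assemble a pipeline run configuration
#'
#' One configuration drives a whole multi-corpus run: which corpora, which
#' year range, which word lists per construct, the control construct, the
#' common-word references, and the data source.
#'
#' @param data_source `"synthetic"`, `"viewer_json"`, `"raw_tsv"` or
#'   `"cache"`.
#' @param corpora corpus labels.
#' @param year_start,year_end inclusive year range (`year_end >=
#'   year_start + 2`).
#' @param constructs for file-backed sources: named list mapping construct
#'   to a named list of per-corpus word-list paths.  For the synthetic
#'   source: named list mapping construct to `list(n_words, trend_slope,
#'   latent_loading)`.
#' @param control_construct control construct label (for example
#'   `"religion"`), or `NULL`.
#' @param common_words named character vector corpus -> reference word;
#'   defaults to [default_common_words()] (or `the_common_word` for the
#'   synthetic source).
#' @param aggregation `"mean"` or `"sum"` word aggregation.
#' @param smoothing Viewer smoothing (0 = raw yearly values).
#' @param seed integer seed for the synthetic source.
#' @param sources source-specific inputs: for `viewer_json` a named list
#'   corpus -> payload path; for `raw_tsv` a named list corpus ->
#'   `list(ngram = path, totals = path)`; for `cache` a list with
#'   `cache_dir`.
#' @param synthetic extra [synthetic_truth()] arguments (e.g. `noise_sd`,
#'   `latent`, `inflation`) for the synthetic source.
#' @param rolling_window,rolling_align rolling-mean diagnostic settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(data_source = c("synthetic", "viewer_json",
                                       "raw_tsv", "cache"),
                       corpora = c("en-GB-2019", "de-2019", "es-2019",
                                   "ru-2019", "fr-2019", "it-2019"),
                       year_start = 1970L, year_end = 2019L,
                       constructs = NULL,
                       control_construct = "religion",
                       common_words = NULL,
                       aggregation = c("mean", "sum"),
                       smoothing = 0L,
                       seed = 1L,
                       sources = list(),
                       synthetic = list(),
                       rolling_window = 5L,
                       rolling_align = c("trailing", "centered")) {
  data_source <- match.arg(data_source)
  aggregation <- match.arg(aggregation)
  rolling_align <- match.arg(rolling_align)
  if (is.null(constructs) && data_source == "synthetic") {
    constructs <- formals(synthetic_truth)$constructs
    constructs <- eval(constructs)
  }
  if (is.null(common_words)) {
    common_words <- if (data_source == "synthetic") {
      stats::setNames(rep("the_common_word", length(corpora)), corpora)
    } else {
      default_common_words()
    }
  }
  structure(
    list(data_source = data_source, corpora = corpora,
         year_start = as.integer(year_start),
         year_end = as.integer(year_end),
         constructs = constructs, control_construct = control_construct,
         common_words = common_words, aggregation = aggregation,
         smoothing = as.integer(smoothing), seed = as.integer(seed),
         sources = sources, synthetic = synthetic,
         rolling_window = as.integer(rolling_window),
         rolling_align = rolling_align),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#' @param path YAML config path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$common_words)) raw$common_words <- unlist(raw$common_words)
  do.call(run_config, raw)
}

#' Validate a run configuration
#'
#' Pure check: returns the list of problems (empty means valid) instead of
#' raising.
#'
#' @param config a [run_config()].
#' @return Character vector of problems.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  if (!inherits(config, "run_config")) {
    return("not a run_config object")
  }
  if (config$year_end < config$year_start + 2L) {
    problems <- c(problems, "year_end must be at least year_start + 2")
  }
  if (length(config$corpora) == 0L) {
    problems <- c(problems, "no corpora configured")
  }
  miss_cw <- setdiff(config$corpora, names(config$common_words))
  if (length(miss_cw)) {
    problems <- c(problems, paste0("no common word configured for: ",
                                   paste(miss_cw, collapse = ", ")))
  }
  if (is.null(config$constructs) || length(config$constructs) == 0L ||
      is.null(names(config$constructs))) {
    problems <- c(problems, "no constructs configured")
  } else if (!is.null(config$control_construct) &&
             !config$control_construct %in% names(config$constructs)) {
    problems <- c(problems, paste0("control construct '",
                                   config$control_construct,
                                   "' has no word list configured"))
  }
  if (config$data_source %in% c("viewer_json", "raw_tsv")) {
    miss_src <- setdiff(config$corpora, names(config$sources))
    if (length(miss_src)) {
      problems <- c(problems, paste0("no source input for corpora: ",
                                     paste(miss_src, collapse = ", ")))
    }
    for (cor in intersect(config$corpora, names(config$sources))) {
      src <- config$sources[[cor]]
      paths <- if (config$data_source == "viewer_json") src
               else unlist(src[c("ngram", "totals")])
      for (p in paths) {
        if (!is.character(p) || !file.exists(p)) {
          problems <- c(problems,
                        paste0("missing input file for ", cor, ": ", p))
        }
      }
    }
  }
  if (config$data_source != "synthetic" &&
      length(config$constructs) && !is.null(names(config$constructs))) {
    for (cons in names(config$constructs)) {
      for (cor in config$corpora) {
        p <- config$constructs[[cons]][[cor]]
        if (is.null(p) || !is.character(p) || !file.exists(p)) {
          problems <- c(problems, sprintf(
            "missing word list for %s/%s", cons, cor))
        }
      }
    }
  }
  if (config$data_source == "cache" &&
      (is.null(config$sources$cache_dir) ||
       !dir.exists(config$sources$cache_dir))) {
    problems <- c(problems, "cache source needs an existing sources$cache_dir")
  }
  problems
}

load_run_inputs <- function(config) {
  years <- seq.int(config$year_start, config$year_end)
  panels <- list(); lexicons <- list(); truth <- NULL
  if (config$data_source == "synthetic") {
    args <- c(list(seed = config$seed, n_years = length(years),
                   year_start = config$year_start,
                   languages = config$corpora,
                   constructs = config$constructs),
              config$synthetic)
    gen <- generate_panel(do.call(synthetic_truth, args))
    panels <- gen$panels
    truth <- gen$truth
    for (cons in names(config$constructs)) {
      lexicons[[cons]] <- lapply(
        stats::setNames(config$corpora, config$corpora),
        function(lang) synthetic_lexicon(truth, cons, lang))
    }
  } else {
    for (cons in names(config$constructs)) {
      lexicons[[cons]] <- lapply(
        stats::setNames(config$corpora, config$corpora),
        function(lang) read_lexicon(config$constructs[[cons]][[lang]],
                                    construct = cons, language = lang))
    }
    for (lang in config$corpora) {
      words <- unique(c(
        unlist(lapply(lexicons, function(by_lang) {
          filtered_words(by_lang[[lang]])
        })),
        config$common_words[[lang]]))
      panels[[lang]] <- switch(
        config$data_source,
        viewer_json = parse_viewer_json(config$sources[[lang]],
                                        config$year_start, config$year_end,
                                        language = lang),
        raw_tsv = parse_raw_ngram(
          config$sources[[lang]]$ngram,
          read_total_counts(config$sources[[lang]]$totals),
          config$year_start, config$year_end, words, language = lang),
        cache = fetch_panel(words, lang, config$year_start, config$year_end,
                            cache_dir = config$sources$cache_dir,
                            smoothing = config$smoothing, offline = TRUE))
    }
  }
  list(panels = panels, lexicons = lexicons, truth = truth, years = years)
}

#' Run the full analysis pipeline
#'
#' Executes lexicon loading, panel assembly, most-common-word adjustment,
#' per-language composites, cross-language pooling, correlation matrices
#' (per language and pooled, against the year index and the control), and
#' per-word rolling means; writes `composites.csv`, `correlations.csv`,
#' `rolling.csv` and a `manifest.json` carrying the configuration, seed and
#' soft issues so the run is reproducible.  With the synthetic source and a
#' fixed seed, two runs produce byte-identical CSVs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return An object of class `ngram_run`: paths of the emitted artifacts
#'   plus the in-memory composites, correlation matrices and truth.
#' @export
run_pipeline <- function(config, out_dir) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  soft <- character(0)
  inputs <- withCallingHandlers(
    load_run_inputs(config),
    warning = function(w) {
      soft <<- c(soft, conditionMessage(w)); invokeRestart("muffleWarning")
    })

  composites <- list()   # construct -> language -> composite_series
  construct_of <- list() # language -> named map word -> construct
  for (lang in config$corpora) {
    adjusted <- common_word_adjust(inputs$panels[[lang]],
                                   config$common_words[[lang]])
    cmap <- character(0)
    for (cons in names(config$constructs)) {
      lex <- inputs$lexicons[[cons]][[lang]]
      composites[[cons]][[lang]] <- withCallingHandlers(
        composite(adjusted, lex, aggregation = config$aggregation),
        warning = function(w) {
          soft <<- c(soft, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      cmap[filtered_words(lex)] <- cons
    }
    construct_of[[lang]] <- cmap
  }
  pooled <- lapply(composites, pool_languages)

  cons_names <- names(config$constructs)
  matrices <- list()
  for (lang in config$corpora) {
    per_lang <- lapply(stats::setNames(cons_names, cons_names),
                       function(cons) composites[[cons]][[lang]])
    matrices[[lang]] <- correlation_matrix(per_lang, inputs$years,
                                           control = config$control_construct)
  }
  matrices$pooled <- correlation_matrix(pooled, inputs$years,
                                        control = config$control_construct)

  rolling <- do.call(rbind, lapply(config$corpora, function(lang) {
    keep <- rownames(inputs$panels[[lang]]$values) %in%
      names(construct_of[[lang]])
    p <- inputs$panels[[lang]]
    p$values <- p$values[keep, , drop = FALSE]
    p$observed <- p$observed[keep, , drop = FALSE]
    panel_rolling_means(p, window = config$rolling_window,
                        align = config$rolling_align,
                        construct_of = construct_of[[lang]])
  }))

  paths <- list(
    composites = file.path(out_dir, "composites.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    rolling = file.path(out_dir, "rolling.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  all_series <- c(unlist(composites, recursive = FALSE, use.names = FALSE),
                  unname(pooled))
  write_composite_csv(all_series, paths$composites)
  cor_long <- do.call(rbind, lapply(names(matrices), function(lang) {
    cor_matrix_long(matrices[[lang]], language = lang)
  }))
  utils::write.csv(cor_long, paths$correlations, row.names = FALSE)
  utils::write.csv(rolling, paths$rolling, row.names = FALSE)

  cfg_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), cfg_tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(
    package = "ngramtrends",
    package_version = as.character(utils::packageVersion("ngramtrends")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    soft_issues = soft,
    outputs = lapply(paths[c("composites", "correlations", "rolling")],
                     function(p) unname(tools::md5sum(p)))
  )
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)

  structure(
    list(paths = paths, config = config, composites = composites,
         pooled = pooled, matrices = matrices, truth = inputs$truth,
         soft_issues = soft),
    class = "ngram_run"
  )
}

#' @export
print.ngram_run <- function(x, ...) {
  cat(sprintf("<ngram_run> %s source, %d corpora, %d constructs, %d-%d\n",
              x$config$data_source, length(x$config$corpora),
              length(x$config$constructs),
              x$config$year_start, x$config$year_end))
  cat("Pooled correlation matrix:\n")
  print(x$matrices$pooled)
  if (length(x$soft_issues)) {
    cat(sprintf("%d soft issue(s) recorded in the manifest\n",
                length(x$soft_issues)))
  }
  cat("Artifacts:\n")
  for (p in x$paths) cat("  ", p, "\n")
  invisible(x)
}
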