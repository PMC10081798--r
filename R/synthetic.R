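#' Ground truth for synthetic ngram panels
#'
#' Describes a fully seeded generative model for multi-language,
#' multi-construct frequency panels.  Word `w` of construct `c` in year index
#' `t = 0, 1, ...` gets
#'
#'   `frequency = inflation(t) * exp(alpha_w + slope_c * t + lambda_c * L(t) + eps_wt)`
#'
#' with `L(t)` a latent path shared by all constructs (and languages) with
#' nonzero loading, and `eps_wt` iid Gaussian noise.  The log-normal
#' construction keeps every frequency positive, and slopes act on the log
#' scale so rising word use is multiplicative, matching the visual character
#' of real Ngram curves.  The per-year `inflation` multiplier emulates the
#' influx of data as the corpus grows; it hits every word including the most
#' common word, so the most-common-word adjustment can cancel it exactly.
#'
#' The latent path is by default a Gaussian random walk standardized to zero
#' mean and unit sample variance, giving the shared component realistic
#' autocorrelation; `latent = "iid"` switches to standardized iid draws for
#' clean type-I-error studies (trend correlation behaves very differently
#' under autocorrelation, so both regimes are generatable).
#'
#' @param seed integer RNG seed; the same truth always generates bit-identical
#'   panels.
#' @param n_years number of years (default 50).
#' @param year_start first year (default 1970).
#' @param languages corpus labels to generate panels for.
#' @param constructs named list; each element a list with `n_words`,
#'   `trend_slope` (per-year, log scale) and `latent_loading` (in `[0, 1]`).
#' @param noise_sd standard deviation of the word-year noise (log scale).
#' @param inflation numeric vector of length `n_years` of positive per-year
#'   multipliers applied to all words; default doubles the corpus over the
#'   span.
#' @param common_word_level baseline frequency (percent) of the most common
#'   word; must dominate every generated word in every year.
#' @param common_word_noise_sd small log-scale noise on the common word.
#' @param base_log_level mean of the word baselines `alpha_w` (log percent).
#' @param alpha_sd spread of the word baselines.
#' @param latent `"random_walk"` or `"iid"`.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed,
                            n_years = 50L,
                            year_start = 1970L,
                            languages = c("en-GB-2019", "de-2019", "es-2019",
                                          "ru-2019", "fr-2019", "it-2019"),
                            constructs = list(
                              anxiety = list(n_words = 13L, trend_slope = 0.03,
                                             latent_loading = 0.2),
                              depression = list(n_words = 13L, trend_slope = 0.03,
                                                latent_loading = 0.2),
                              digitalization = list(n_words = 33L, trend_slope = 0.04,
                                                    latent_loading = 0.2),
                              religion = list(n_words = 19L, trend_slope = 0,
                                              latent_loading = 0)
                            ),
                            noise_sd = 0.3,
                            inflation = NULL,
                            common_word_level = 0.5,
                            common_word_noise_sd = 0.01,
                            base_log_level = log(0.002),
                            alpha_sd = 0.5,
                            latent = c("random_walk", "iid")) {
  latent <- match.arg(latent)
  n_years <- as.integer(n_years)
  stopifnot(n_years >= 3L, noise_sd > 0, length(languages) >= 1L,
            length(constructs) >= 1L, !is.null(names(constructs)))
  if (is.null(inflation)) {
    inflation <- exp(log(2) * (seq_len(n_years) - 1L) / (n_years - 1L))
  }
  stopifnot(length(inflation) == n_years, all(inflation > 0))
  for (nm in names(constructs)) {
    cc <- constructs[[nm]]
    stopifnot(cc$n_words >= 1L,
              cc$latent_loading >= 0, cc$latent_loading <= 1)
  }
  stopifnot(common_word_level > 0, common_word_noise_sd >= 0)
  structure(
    list(seed = as.integer(seed), n_years = n_years,
         year_start = as.integer(year_start),
         languages = languages, constructs = constructs,
         noise_sd = noise_sd, inflation = inflation,
         common_word_level = common_word_level,
         common_word_noise_sd = common_word_noise_sd,
         base_log_level = base_log_level, alpha_sd = alpha_sd,
         latent = latent),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> seed %d: %d languages x %d constructs x %d years (%s latent)\n",
    x$seed, length(x$languages), length(x$constructs), x$n_years, x$latent))
  invisible(x)
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Generate synthetic frequency panels with known ground truth
#'
#' Draws one latent path, then per language one panel holding every
#' construct's words plus the corpus's most common word.  Word rows are named
#' `<construct>_w01`, `<construct>_w02`, ...; the common word row is named
#' `the_common_word`.  The returned truth carries a `word_map` from construct
#' to its row names so downstream lexicons can be built with
#' [synthetic_lexicon()].
#'
#' Generation fails if any word exceeds the common word in any year (the
#' common word must dominate by construction, as in real corpora).
#'
#' @param truth a [synthetic_truth()].
#' @return List with `panels` (named list of [freq_panel()], one per
#'   language) and `truth` (the input plus `word_map` and `latent_path`).
#' @export
generate_panel <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(truth$seed, {
    T <- truth$n_years
    years <- seq.int(truth$year_start, length.out = T)
    tt <- seq_len(T) - 1L
    L <- if (truth$latent == "random_walk") cumsum(stats::rnorm(T))
         else stats::rnorm(T)
    L <- (L - mean(L)) / stats::sd(L)  # standardized shared path

    word_map <- lapply(truth$constructs, function(cc) NULL)
    panels <- vector("list", length(truth$languages))
    names(panels) <- truth$languages
    for (lang in truth$languages) {
      blocks <- vector("list", length(truth$constructs) + 1L)
      for (ci in seq_along(truth$constructs)) {
        cname <- names(truth$constructs)[ci]
        cc <- truth$constructs[[cname]]
        nw <- as.integer(cc$n_words)
        wnames <- sprintf("%s_w%02d", cname, seq_len(nw))
        word_map[[cname]] <- wnames
        alpha <- stats::rnorm(nw, truth$base_log_level, truth$alpha_sd)
        eps <- matrix(stats::rnorm(nw * T, 0, truth$noise_sd), nw, T)
        logf <- outer(alpha, cc$trend_slope * tt, "+") +
          matrix(cc$latent_loading * L, nw, T, byrow = TRUE) + eps
        blocks[[ci]] <- exp(logf) *
          matrix(truth$inflation, nw, T, byrow = TRUE)
        rownames(blocks[[ci]]) <- wnames
      }
      cw <- truth$common_word_level *
        exp(stats::rnorm(T, 0, truth$common_word_noise_sd)) * truth$inflation
      blocks[[length(blocks)]] <- matrix(cw, 1L, T,
                                         dimnames = list("the_common_word",
                                                         NULL))
      values <- do.call(rbind, blocks)
      colnames(values) <- years
      over <- sweep(values[rownames(values) != "the_common_word", ,
                           drop = FALSE], 2L, cw, ">=")
      if (any(over)) {
        stop("synthetic parameters make the common word non-dominant in ",
             lang, " (raise common_word_level or lower word levels)")
      }
      panels[[lang]] <- freq_panel(values, lang, years)
    }
    truth$word_map <- word_map
    truth$latent_path <- L
    list(panels = panels, truth = truth)
  })
}

#' Lexicon for a synthetic construct
#'
#' @param truth the truth returned by [generate_panel()] (must carry
#'   `word_map`).
#' @param construct construct name.
#' @param language corpus label to stamp on the lexicon.
#' @return A `lexicon` including every generated word of the construct.
#' @export
synthetic_lexicon <- function(truth, construct, language) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.null(truth$word_map),
            construct %in% names(truth$word_map))
  new_lexicon(construct, language, data.frame(
    word = truth$word_map[[construct]],
    include = TRUE, exclusion_reason = "none",
    stringsAsFactors = FALSE
  ))
}

#' Apply year-wise corpus-inflation multipliers to a panel
#'
#' Multiplies every cell of year `t` (including the common word's) by
#' `factors[t]`, emulating growth of the underlying corpus.  The
#' most-common-word adjustment cancels this exactly:
#' `common_word_adjust(inflate_panel(p, f))` equals
#' `common_word_adjust(p)`.
#'
#' @param panel a [freq_panel()].
#' @param factors positive numeric vector, one multiplier per panel year
#'   (optionally named by year).
#' @return The inflated [freq_panel()].
#' @export
inflate_panel <- function(panel, factors) {
  stopifnot(inherits(panel, "freq_panel"))
  if (!is.null(names(factors))) {
    factors <- factors[as.character(panel$years)]
    if (anyNA(factors)) stop("factors do not cover all panel years")
  }
  if (length(factors) != length(panel$years)) {
    stop("need one factor per panel year")
  }
  if (any(!is.finite(factors) | factors <= 0)) {
    stop("inflation factors must be positive and finite")
  }
  panel$values <- sweep(panel$values, 2L, factors, "*")
  panel
}

#' Write the ground truth sidecar
#' @param truth a [synthetic_truth()].
#' @param path output JSON path (conventionally `truth.json`).
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
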