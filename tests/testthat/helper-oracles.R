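# Independent brute-force oracles. These deliberately avoid the package's
# implementations (and vectorized shortcuts) so agreement is informative.

# Pearson r and two-sided p from the explicit sums formula and the t CDF.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; syy <- syy + y[i]^2; sxy <- sxy + x[i] * y[i]
  }
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  r <- num / den
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

# Two-pass z-score with the sample sd written out.
oracle_zscore <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  (x - m) / s
}

# Per-window mean loop.
oracle_rollmean <- function(x, k) {
  n <- length(x)
  out <- numeric(n - k + 1)
  for (i in k:n) out[i - k + 1] <- mean(x[(i - k + 1):i])
  out
}

# Small null-world truth: two unrelated constructs, one language.
null_truth <- function(seed, n_words = 10L, n_years = 50L,
                       noise_sd = 0.3, latent = "iid") {
  synthetic_truth(
    seed, n_years = n_years, languages = "L1",
    constructs = list(
      a = list(n_words = n_words, trend_slope = 0, latent_loading = 0),
      b = list(n_words = n_words, trend_slope = 0, latent_loading = 0)),
    noise_sd = noise_sd, latent = latent)
}

# Composite pair r for one synthetic replicate, via the package pipeline.
pipeline_pair_r <- function(truth) {
  g <- generate_panel(truth)
  adj <- common_word_adjust(g$panels[[1L]], "the_common_word")
  ca <- composite(adj, synthetic_lexicon(g$truth, "a", "L1"))
  cb <- composite(adj, synthetic_lexicon(g$truth, "b", "L1"))
  pearson_cor(ca$values, cb$values)
}

# Write a word-list TSV from vectors; returns the path.
write_wordlist <- function(path, word, include = TRUE,
                           exclusion_reason = NULL) {
  n <- length(word)
  include <- rep_len(include, n)
  if (is.null(exclusion_reason)) {
    exclusion_reason <- ifelse(include, "none", "other")
  }
  df <- data.frame(word = word,
                   include = ifelse(include, "true", "false"),
                   exclusion_reason = exclusion_reason,
                   notes = "", inflections = "",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

extdata <- function(name) {
  system.file("extdata", name, package = "ngramtrends", mustWork = TRUE)
}
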