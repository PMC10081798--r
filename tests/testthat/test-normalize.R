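test_that("common-word adjustment divides by the reference series", {
  years <- 1970:1974
  values <- rbind(fear = c(2, 4, 6, 8, 10),
                  echo = c(10, 20, 30, 40, 50),  # same shape as the reference
                  time = c(10, 20, 30, 40, 50))
  panel <- freq_panel(values, "en-GB-2019", years)
  adj <- common_word_adjust(panel, "time")
  expect_equal(adj$unit, "ratio")
  expect_false("time" %in% panel_words(adj))
  # a word proportional to the reference becomes a constant ratio
  expect_equal(unname(adj$values["echo", ]), rep(1, 5))
  expect_equal(unname(adj$values["fear", ]), values["fear", ] / values["time", ])

  expect_error(common_word_adjust(panel, "Zeit"), "missing")
  values2 <- values; values2["time", 2] <- 0
  p2 <- freq_panel(values2, "en-GB-2019", years)
  expect_error(common_word_adjust(p2, "time"), "1971")
})

test_that("corpus inflation cancels exactly through the adjustment", {
  set.seed(21)
  for (i in 1:5) {
    g <- generate_panel(null_truth(300 + i, n_words = 6L, n_years = 20L))
    panel <- g$panels[[1]]
    f <- runif(20, 0.2, 5)
    a1 <- common_word_adjust(panel, "the_common_word")
    a2 <- common_word_adjust(inflate_panel(panel, f), "the_common_word")
    expect_equal(a2$values, a1$values, tolerance = 1e-12)
  }
})

test_that("z-scores have mean zero and unit sample sd", {
  expect_equal(zscore_series(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore_series(c(5, 5, 5)), "constant series")
  expect_error(zscore_series(3), "length >= 2")

  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(50, sd = runif(1, 0.1, 10))
    z <- zscore_series(x)
    expect_equal(z, oracle_zscore(x), tolerance = 1e-12)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(stats::sd(z) - 1), 1e-12)
  }
})

test_that("composites average z-scored word series", {
  years <- 1970:1979
  base <- sin(1:10) + 2
  values <- rbind(w1 = base, w2 = base * 3,  # same shape after z-scoring
                  cw = rep(10, 10))
  panel <- freq_panel(values, "L1", years, unit = "ratio")
  lex <- new_lexicon("a", "L1", data.frame(
    word = c("w1", "w2"), include = TRUE, exclusion_reason = "none"))
  cs <- composite(panel, lex)
  expect_s3_class(cs, "composite_series")
  expect_equal(cs$values, zscore_series(base), tolerance = 1e-12)
  expect_equal(cs$n_words, 2L)
  # single-language composite is centered by construction
  expect_lt(abs(mean(cs$values)), 1e-9)

  # mirror series cancel
  up <- 1:10; down <- 21 - (1:10)
  p2 <- freq_panel(rbind(w1 = up, w2 = down), "L1", years, unit = "ratio")
  cs2 <- composite(p2, lex)
  expect_equal(cs2$values, rep(0, 10), tolerance = 1e-12)
})

test_that("composites are invariant to lexicon word order", {
  g <- generate_panel(null_truth(44, n_words = 8L, n_years = 15L))
  adj <- common_word_adjust(g$panels[[1]], "the_common_word")
  words <- g$truth$word_map$a
  mk <- function(w) new_lexicon("a", "L1", data.frame(
    word = w, include = TRUE, exclusion_reason = "none"))
  c1 <- composite(adj, mk(words))
  c2 <- composite(adj, mk(rev(words)))
  expect_equal(c1$values, c2$values, tolerance = 1e-12)
})

test_that("sum and mean aggregation differ only by the word count", {
  g <- generate_panel(null_truth(45, n_words = 7L, n_years = 20L))
  adj <- common_word_adjust(g$panels[[1]], "the_common_word")
  lex <- synthetic_lexicon(g$truth, "a", "L1")
  cm <- composite(adj, lex, aggregation = "mean")
  cs <- composite(adj, lex, aggregation = "sum")
  expect_equal(cs$values, cm$values * cm$n_words, tolerance = 1e-12)
})

test_that("zero-variance words are dropped or fail per policy", {
  years <- 1970:1979
  panel <- freq_panel(rbind(w1 = sin(1:10) + 2, w2 = rep(0.5, 10)),
                      "L1", years, unit = "ratio")
  lex <- new_lexicon("a", "L1", data.frame(
    word = c("w1", "w2"), include = TRUE, exclusion_reason = "none"))
  expect_warning(cs <- composite(panel, lex), "zero-variance")
  expect_equal(cs$n_words, 1L)
  expect_error(composite(panel, lex, zero_variance = "fail"),
               "zero-variance")
  flat <- freq_panel(rbind(w1 = rep(1, 10), w2 = rep(0.5, 10)),
                     "L1", years, unit = "ratio")
  expect_error(suppressWarnings(composite(flat, lex)), "no usable words")

  lex2 <- new_lexicon("a", "L1", data.frame(
    word = "absent", include = TRUE, exclusion_reason = "none"))
  expect_error(composite(panel, lex2), "missing from panel")
})

test_that("pooling averages language composites year by year", {
  g <- generate_panel(synthetic_truth(
    46, n_years = 12L, languages = c("L1", "L2", "L3"),
    constructs = list(a = list(n_words = 5L, trend_slope = 0.02,
                               latent_loading = 0.5))))
  per_lang <- lapply(names(g$panels), function(lang) {
    adj <- common_word_adjust(g$panels[[lang]], "the_common_word")
    composite(adj, synthetic_lexicon(g$truth, "a", lang))
  })
  pooled <- pool_languages(per_lang)
  expect_equal(pooled$language, "pooled")
  expect_equal(pooled$n_languages, 3L)
  expect_equal(pooled$values,
               rowMeans(sapply(per_lang, `[[`, "values")),
               tolerance = 1e-12)
  # one language pools to itself
  p1 <- pool_languages(per_lang[1])
  expect_equal(p1$values, per_lang[[1]]$values)
  # identical composites pool to the same series
  p2 <- pool_languages(per_lang[c(1, 1)])
  expect_equal(p2$values, per_lang[[1]]$values, tolerance = 1e-12)

  other <- per_lang[[2]]; other$construct <- "b"
  expect_error(pool_languages(list(per_lang[[1]], other)), "mixed constructs")
  shifted <- per_lang[[2]]; shifted$years <- shifted$years + 1L
  expect_error(pool_languages(list(per_lang[[1]], shifted)),
               "mismatched year ranges")
})

test_that("pooled composites track a strong shared latent path", {
  tr <- synthetic_truth(
    47, n_years = 50L, languages = paste0("L", 1:6),
    constructs = list(a = list(n_words = 10L, trend_slope = 0,
                               latent_loading = 1)),
    noise_sd = 0.5)
  g <- generate_panel(tr)
  per_lang <- lapply(names(g$panels), function(lang) {
    adj <- common_word_adjust(g$panels[[lang]], "the_common_word")
    composite(adj, synthetic_lexicon(g$truth, "a", lang))
  })
  pooled <- pool_languages(per_lang)
  # tracking is strong but not perfect: words live on the exp scale, so the
  # z-scored ratios are a convex transform of the latent path
  r <- pearson_cor(pooled$values, g$truth$latent_path)$r
  expect_gt(r, 0.85)
})
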