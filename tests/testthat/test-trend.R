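test_that("pearson_cor handles exact linearity and input contracts", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$p, 0)

  x <- rnorm(20)
  expect_error(pearson_cor(x, rnorm(19)), "lengths differ")
  expect_error(pearson_cor(x[1:2], x[1:2]), "n >= 3")
  expect_error(pearson_cor(x, rep(1, 20)), "zero variance")

  set.seed(61)
  for (i in 1:20) {
    x <- rnorm(15); y <- 0.4 * x + rnorm(15)
    a <- pearson_cor(x, y); b <- pearson_cor(y, x)
    expect_equal(a$r, b$r)
    expect_equal(a$p, b$p)
    # affine recoding of either input leaves r and p unchanged
    c2 <- pearson_cor(3.7 * x - 11, y)
    expect_equal(c2$r, a$r, tolerance = 1e-12)
    expect_equal(c2$p, a$p, tolerance = 1e-12)
    expect_equal(pearson_cor(x, -2 * x + 5)$r, -1)
  }
})

test_that("pearson_cor matches the explicit-sums oracle on fixed series", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  got <- pearson_cor(x, y)
  want <- oracle_pearson(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$n, 10L)
})

test_that("significance stars follow the .05/.01/.001 thresholds", {
  expect_equal(ngramtrends:::p_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
  # boundary values are not starred (strict inequality)
  expect_equal(ngramtrends:::p_stars(c(0.05, 0.01, 0.001)),
               c("", "*", "**"))
})

test_that("correlation matrices mirror the constructs/Years/control layout", {
  yrs <- 1970:2019
  lin <- as.numeric(scale(yrs))
  set.seed(62)
  noise <- rnorm(50)
  m <- correlation_matrix(
    list(anxiety = lin, anxiety_copy = lin, religion = noise),
    year_index = yrs, control = "religion")
  expect_equal(m$labels, c("anxiety", "anxiety_copy", "Years", "religion"))
  expect_equal(m$r["anxiety_copy", "anxiety"], 1)
  # a construct exactly linear in year correlates perfectly with Years
  expect_equal(m$r["Years", "anxiety"], 1)
  expect_equal(m$stars["Years", "anxiety"], "***")
  expect_true(all(abs(m$r) <= 1, na.rm = TRUE))
  expect_true(all(m$p >= 0 & m$p <= 1, na.rm = TRUE))
  # symmetric with unit diagonal; Holm p never below the raw p
  expect_equal(m$r, t(m$r))
  expect_equal(unname(diag(m$r)), rep(1, 4))
  off <- lower.tri(m$p)
  expect_true(all(m$holm_p[off] >= m$p[off]))

  long <- cor_matrix_long(m, language = "pooled")
  expect_equal(nrow(long), choose(4, 2))
  expect_named(long, c("pair_a", "pair_b", "language", "r", "p", "n",
                       "stars", "holm_p"))
})

test_that("failed cells are recorded instead of aborting the matrix", {
  m <- correlation_matrix(list(a = c(1, 2, 3, 4), b = rep(1, 4),
                               c = c(2, 1, 4, 3)))
  expect_length(m$failed, 2L)
  expect_true(is.na(m$r["b", "a"]))
  expect_false(is.na(m$r["c", "a"]))
})

test_that("rolling means average trailing windows", {
  rm5 <- rolling_mean(1:10, window = 5, years = 2001:2010)
  expect_equal(rm5$values, c(3, 4, 5, 6, 7, 8))
  expect_equal(rm5$years, 2005:2010)
  expect_length(rm5$values, 10 - 5 + 1)

  rm1 <- rolling_mean(1:10, window = 1)
  expect_equal(rm1$values, as.numeric(1:10))

  set.seed(63)
  for (i in 1:10) {
    x <- rnorm(50)
    k <- sample(2:8, 1)
    expect_equal(rolling_mean(x, k)$values, oracle_rollmean(x, k),
                 tolerance = 1e-12)
  }

  cen <- rolling_mean(1:10, window = 5, years = 2001:2010,
                      align = "centered")
  expect_equal(cen$values, c(3, 4, 5, 6, 7, 8))
  expect_equal(cen$years, 2003:2008)
  expect_error(rolling_mean(1:3, window = 5), "shorter than")
  expect_error(rolling_mean(1:10, window = 4, align = "centered"), "odd")
})

test_that("trend labels use strict epsilon thresholds on the OLS slope", {
  expect_equal(trend_label(seq(1, 5, length.out = 20)), "increase")
  expect_equal(trend_label(seq(5, 1, length.out = 20)), "decrease")
  expect_equal(trend_label(rep(2, 10)), "flat")
  # slope exactly +epsilon stays flat (strict inequality)
  x <- 0.5 * (1:10)  # slope 0.5, range 4.5 -> default eps 0.045
  expect_equal(trend_label(x, slope_epsilon = 0.5), "flat")
  expect_equal(trend_label(x, slope_epsilon = 0.4999), "increase")
})

test_that("panel rolling means cover every word with metadata", {
  g <- generate_panel(null_truth(64, n_words = 3L, n_years = 12L))
  df <- panel_rolling_means(g$panels[[1]], window = 5,
                            construct_of = stats::setNames(
                              rep(c("a", "b"), each = 3),
                              unlist(g$truth$word_map)))
  expect_equal(sort(unique(df$word)),
               sort(panel_words(g$panels[[1]])))
  expect_equal(sum(df$word == "a_w01"), 12 - 5 + 1)
  expect_true(all(df$trend %in% c("increase", "decrease", "flat")))
  expect_equal(unique(df$construct[df$word == "b_w02"]), "b")
})

test_that("autocorrelated series inflate nominal significance (caveat)", {
  # Two composites driven by independent random-walk latents: the yearly
  # Pearson test rejects far more than 5% of true nulls.  Trending or
  # autocorrelated series make per-year correlation tests anticonservative;
  # the iid calibration elsewhere does not transfer to this regime.
  one_walk_composite <- function(seed) {
    g <- generate_panel(synthetic_truth(
      seed, n_years = 50L, languages = "L1",
      constructs = list(a = list(n_words = 5L, trend_slope = 0,
                                 latent_loading = 1)),
      noise_sd = 0.3, latent = "random_walk"))
    adj <- common_word_adjust(g$panels[[1]], "the_common_word")
    composite(adj, synthetic_lexicon(g$truth, "a", "L1"))$values
  }
  p_vals <- vapply(seq_len(300), function(k) {
    pearson_cor(one_walk_composite(70000 + 2 * k),
                one_walk_composite(70001 + 2 * k))$p
  }, numeric(1))
  rate <- mean(p_vals < 0.05)
  message(sprintf(
    "spurious-significance rate under independent random walks: %.2f", rate))
  expect_gt(rate, 0.2)
})
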