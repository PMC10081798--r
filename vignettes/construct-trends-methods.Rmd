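---
title: "Methods: composite word-frequency indices and their trend statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite word-frequency indices and their trend statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngramtrends)
```

## The measurement model

`ngramtrends` treats a psychological or societal construct as a curated
word list and measures its cultural salience as a normalized composite of
those words' yearly relative frequencies in a book corpus.  The raw datum
is the Ngram relative frequency: a word's yearly match count divided by the
corpus's total token count that year, stored here in percent (a word at 1%
of all tokens stores `1.0`).

Three normalization steps turn per-word percent series into one index per
construct and corpus:

1. **Most-common-word adjustment.** Every word's series is divided, year by
   year, by the series of the corpus's most frequent noun ("time", "Zeit",
   "parte", "эго", "temps", "parte" in the default corpus set).  The point
   is influx control: the digitized corpus grows over the years, and any
   per-year multiplicative change in corpus size or composition hits the
   reference word identically, so it cancels in the ratio.  This makes the
   composite *exactly* invariant to year-wise rescaling, which the test
   suite asserts numerically to 1e-9.
2. **Per-word z-transformation** with the sample standard deviation
   (denominator n − 1), so high-frequency words cannot dominate a list.
3. **Aggregation**: the composite is the mean over the list's words of the
   z-scored, adjusted series; the all-language index is the unweighted mean
   of per-language composites.

Trend statistics are sample Pearson correlations between composites and
between each composite and the calendar year, with the two-sided p-value
from `t = r sqrt((n−2)/(1−r²))` on n − 2 degrees of freedom and
`*`/`**`/`***` stars at .05/.01/.001.  A 5-year rolling mean per word, with
an OLS-slope increase/decrease/flat label, serves as a qualitative
non-stationarity diagnostic.

### Order of operations

Captions of this style of analysis name "z-transformed, most common word
controlled" without fixing the order.  We adjust **first**, then z-score.
Rationale: adjusting first makes the influx-invariance property exactly
true, which is the stated purpose of the adjustment; z-scoring first would
leave a residual dependence on the year-wise scale.  (Both orders are
trivially composable from the exported functions if a sensitivity analysis
is wanted.)

### Sum versus mean aggregation

Summed z-scores and list-averaged z-scores differ only by the constant list
size, and Pearson r is invariant to affine rescaling of either argument, so
every downstream correlation is identical to floating-point precision
(asserted to 1e-12).  The mean is the default because it keeps composite
scales comparable across lists of different length.

### Pooling across languages

"Over all languages" is implemented as the unweighted mean of per-language
composites.  The alternative reading — pooling raw words across languages
before aggregation — would weight languages by list length; it can be
reproduced by concatenating lexicons, but it is not the default.

### Other fixed choices

- **Two-sided p-values**: threshold-style star reporting does not state
  sidedness; two-sided is the conservative default.
- **No multiple-testing correction for stars**, matching the per-cell star
  convention of trend-correlation tables; a Holm-adjusted p column is
  emitted alongside for transparency.
- **Year index** enters as calendar years (Pearson r is invariant to its
  affine coding).
- **Trailing rolling windows**: "five consecutive years" does not fix
  alignment; trailing keeps the diagnostic causal.  A centered switch
  exists (odd windows only).
- **Dominance-check tie-break**: when two inflected forms tie on summed
  frequency, the lexicographically first form wins — determinism matters
  more than the (arbitrary) direction.
- **Viewer smoothing defaults to 0**: the correlations are computed on
  yearly values, and smoothing would leak autocorrelation into r.
- **Case handling**: words are compared case-folded for duplicate
  detection but queried verbatim — the Ngram corpora are case-sensitive and
  German nouns are capitalized.
- **Missing (word, year) cells become 0 with an `observed = FALSE` flag**,
  not NA: a word absent from a year's books genuinely has zero relative
  frequency (relevant for digitalization terms before coinage).  The flags
  let reports state coverage.
- **Zero-variance words are dropped per language with a warning** (policy
  `zero_variance = "fail"` available): failing outright would make lists
  containing late-coined terms unprocessable in some corpora.

## Word lists are data, not code

The curation pipeline behind a word list — seed terms from diagnostic
classifications, thesaurus synonym expansion, native-speaker translation
with independent back-translation, exclusion of double meanings and of
synonyms with broader semantic meaning — is human work.  The package only
consumes its outcome, recorded in a TSV dialect with `include` flags and
`exclusion_reason` codes, and never attempts automated translation or
synonym expansion.  The shipped example lists are illustrative fixtures,
not a reconstruction of any published list; list sizes are therefore data,
not constants.  The `_INF` inflection tags support the one automated
consistency check: the curated base form should be the most frequent of its
inflections (`dominance_check()`).

## What the synthetic generator emulates

`synthetic_truth()` + `generate_panel()` produce panels from

```
frequency(w, t) = inflation(t) * exp(alpha_w + slope_c * t + lambda_c * L(t) + eps_wt)
```

with `L(t)` a latent path shared by all loaded constructs (and languages)
and `eps` iid Gaussian on the log scale.  The construction is log-normal so
frequencies stay positive and slopes act multiplicatively, matching the
visual character of real Ngram curves; the per-year `inflation` multiplier
emulates the influx of newly digitized text; a dominant `the_common_word`
row (validated every year at generation time) plays the most-frequent-noun
role.

Default study conditions: 6 corpora, 50 years (1970–2019), constructs
anxiety (13 words), depression (13), digitalization (33) — per-construct
splits of curated lists are supplementary data in the source analyses, so
these counts are illustrative round numbers consistent with a 59-word
combined set — and a 19-word religion control.  Log-slopes are 0.03/0.03/
0.04 per year for the three constructs with latent loading 0.2, and 0/0 for
the control; `noise_sd = 0.3`; corpus size doubles over the span.  These
values were chosen once so that the generated data reproduce the
*character* of the real corpora — trend-dominated construct series whose
year correlations land around .9 and whose pairwise correlations are
high, with a null control — rather than any particular printed number.

The latent path is a Gaussian random walk standardized to mean 0, sample
variance 1, because trend correlation behaves very differently under
autocorrelation; `latent = "iid"` switches to standardized iid draws for
clean calibration studies.  The generator does **not** emulate OCR error,
corpus composition shifts, case-variant merging, or any fitted model of
real Ngram data — so passing tests demonstrate pipeline correctness and
statistical calibration under the stated model, not faithfulness of real
corpora to that model.

## Calibration, recovery, and the non-stationarity caveat

The test suite establishes three statistical facts, all recomputed at run
time:

- **Calibration**: under the iid null (two unrelated 10-word constructs,
  50 years, 10,000 seeded replicates) the fraction of construct-pair tests
  with p < .05 falls within [0.045, 0.055].
- **Recovery**: with both constructs loading fully on one iid latent path
  and `noise_sd = 1.15` — a level chosen so the *true* composite–composite
  correlation, computed by an independent brute-force Monte-Carlo
  simulation of the generative formula, is near 0.8 — the pipeline's mean
  estimated r over 200 replicates agrees with the oracle within 0.02.
  Note the exp-scale nonlinearity matters here: the true correlation of
  the composites is substantially lower than the log-scale signal share
  `1/(1 + sigma^2/n_words)` would suggest.
- **The caveat**: under *independent random-walk* latents the same test
  rejects far more than 5% of true nulls (the suite computes the spurious
  rate; it is several times nominal).  Yearly Pearson tests on trending or
  strongly autocorrelated series are anticonservative, which is exactly why
  a null control construct and the rolling-mean diagnostic belong in the
  workflow.  Detrending, differencing and formal stationarity tests are
  deliberately out of scope here.

## Problem sizes and numerical tolerances

Oracle-equivalence tests run 100 random instances per statistic at 1e-10;
exact invariances (influx, aggregation, word order) are asserted at
1e-9–1e-12; the calibration study uses 10,000 replicates, recovery 200
(against a 1,000-replicate oracle), and the null-control check 1,000 —
sizes at which Monte-Carlo error is comfortably inside each asserted band
while the whole suite stays interactive.  All replicate streams are seeded;
`generate_panel()` restores the caller's RNG state, so package randomness
never perturbs user scripts.

## Known limitations

- Correlation is not causation; the package computes association tables and
  diagnostics, nothing more.
- Pearson p-values assume approximately independent yearly observations;
  see the caveat above.  Stars on real, trending corpus series should be
  read descriptively.
- Only 1-grams are supported (multi-word phrases are too infrequent in
  these corpora to show stable change), and only the `_INF` expansion of
  the Viewer query syntax.
- The online fetcher is cache-first and retries with backoff, but the
  Viewer endpoint is rate-limited and unversioned; archived cache
  directories, not live fetches, are the reproducible path.
- Pooling weights every language equally regardless of corpus size or list
  coverage; `n_words`/`n_languages` fields and coverage flags make the
  ingredients auditable.
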