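# Minimal synthetic-run configuration.
data_source: synthetic
corpora: [en-GB-2019, de-2019, es-2019, ru-2019, fr-2019, it-2019]
year_start: 1970
year_end: 2019
control_construct: religion
aggregation: mean
seed: 1
constructs:
  anxiety: {n_words: 13, trend_slope: 0.03, latent_loading: 0.2}
  depression: {n_words: 13, trend_slope: 0.03, latent_loading: 0.2}
  digitalization: {n_words: 33, trend_slope: 0.04, latent_loading: 0.2}
  religion: {n_words: 19, trend_slope: 0.0, latent_loading: 0.0}
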