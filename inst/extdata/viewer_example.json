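[
  {"ngram": "fear", "parent": "", "type": "NGRAM",
   "timeseries": [0.00010, 0.00011, 0.00012, 0.00013, 0.00014]},
  {"ngram": "fear_INF", "parent": "", "type": "EXPANSION",
   "timeseries": [0.00015, 0.00016, 0.00018, 0.00019, 0.00021]},
  {"ngram": "time", "parent": "", "type": "NGRAM",
   "timeseries": [0.00090, 0.00091, 0.00092, 0.00091, 0.00093]}
]
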