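year,match_count,page_count,volume_count
1970,1000000,5000,100
1971,1050000,5200,104
1972,1100000,5400,108
1973,1160000,5600,113
1974,1220000,5800,118
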