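fear	1970	500	40
fear	1971	550	41
fear	1972	600	44
fear	1974	700	50
worry	1970	200	30
worry	1971	220	31
worry	1972	230	31
worry	1973	260	35
worry	1974	280	36
time	1970	9000	300
time	1971	9100	305
time	1972	9300	310
time	1973	9400	312
time	1974	9600	320
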