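quintile	prop_consumers	mean_cups_per_day	population_share
1	0.447	1.41	0.2
2	0.412	1.18	0.2
3	0.383	0.94	0.2
4	0.342	1.02	0.2
5	0.29	0.72	0.2
total	0.372	1.07	1
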