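1	2999999	3200000	demo_known_1	gain	synthetic_map
2	499999	900000	demo_known_2	gain	synthetic_map
2	1999999	2200000	demo_known_3	loss	synthetic_map
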