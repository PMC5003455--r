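1	1049999	1120000	DEMOA	DEMOA1,DA
1	2599999	2650000	DEMOB	
2	549999	620000	DEMOC	
2	2999999	3050000	DEMOD	
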