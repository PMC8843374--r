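protein_id	domain	start	end
Adk	CORE	1	29
Adk	CORE	60	121
Adk	CORE	160	214
Adk	AMP-binding	30	59
Adk	LID	122	159
Icd	large	1	124
Icd	large	321	416
Icd	small	125	162
Icd	small	200	320
Icd	clasp	163	199
KatE	N-terminal-arm	1	127
KatE	beta-barrel	128	390
KatE	wrapping-loop	391	504
KatE	helical	505	564
KatE	C-terminal	600	753
Fmt	Rossmann	1	189
Fmt	linker	190	208
Fmt	OB-fold	209	314
YaaA	HhH	35	66
YaaA	beta-strand-motif	187	202
YaaA	beta-strand-motif	239	258
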