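protein_id	resno	mechanisms
Adk	136	KAT:YfiQ;KAT:YiaC
Adk	141	AcP
Adk	145	AcP
Adk	157	AcP
Adk	192	AcP
Adk	211	AcP
Icd	4	KAT:YiaC;AcP
Icd	12	AcP
Icd	174	AcP
Icd	177	AcP
Icd	235	AcP
Icd	265	AcP
Icd	378	KAT:YiaC
KatE	56	KAT:YfiQ;KAT:YiaC
KatE	64	KAT:YfiQ
Fmt	45	KAT:YfiQ;KAT:YiaC
Fmt	46	KAT:YfiQ;KAT:YiaC
YaaA	55	KAT:YfiQ;KAT:YiaC
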