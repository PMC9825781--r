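id	axis	preferred_label	synonyms	xrefs
DEMO:0000001	DIS	covid-19	coronavirus disease 2019|covid19 pandemic disease	MONDO:0100096
CHEBI:145994	CHEM	remdesivir	GS-5734	DRUGBANK:DB14761
NCBITaxon:2697049	ORG	severe acute respiratory syndrome coronavirus 2	SARS-CoV-2
DEMO:0000002	PG	spike glycoprotein	S protein	UNIPROT:P0DTC2
DEMO:0000003	GL	wuhan		GEO:000003
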