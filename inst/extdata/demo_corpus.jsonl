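{"doc_id":"doc1","collection":"demo","title":"Remdesivir for the treatment of covid-19","abstract":"Remdesivir (GS-5734) inhibits SARS-CoV-2 replication in vitro and shortened recovery time in hospitalised covid-19 patients."}
{"doc_id":"doc2","collection":"demo","title":"Structure of the spike glycoprotein","abstract":"The SARS-CoV-2 spike glycoprotein mediates cell entry and is the principal target of neutralising antibodies elicited by COVID19 infection."}
{"doc_id":"doc3","collection":"demo","title":"Early epidemiology of an outbreak of pneumonia","abstract":"A cluster of pneumonia cases in Wuhan was linked to a novel coronavirus, later designated severe acute respiratory syndrome coronavirus 2."}
{"doc_id":"doc4","collection":"demo","title":"Influenza vaccination coverage","abstract":"Seasonal influenza vaccination coverage remained stable; no coronavirus-related admissions were recorded in this cohort."}
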