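gene_symbol,n_studies,fibroblast_discriminant
ADAMTS5,2,FALSE
COL4A1,3,TRUE
COL5A1,3,TRUE
LOXL2,2,TRUE
TAGLN,2,TRUE
PLOD2,2,TRUE
PRRX1,2,FALSE
CAND01,2,FALSE
CAND02,2,FALSE
CAND03,2,FALSE
CAND04,2,FALSE
CAND05,2,FALSE
CAND06,2,FALSE
CAND07,2,FALSE
CAND08,2,FALSE
CAND09,2,FALSE
CAND10,2,FALSE
CAND11,2,FALSE
CAND12,2,FALSE
CAND13,2,FALSE
CAND14,2,FALSE
CAND15,2,FALSE
CAND16,2,FALSE
CAND17,2,FALSE
CAND18,3,FALSE
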