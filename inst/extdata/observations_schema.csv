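column,type,description
strain,character,"strain label: WT or DD (Mrs3/4 double deletion)"
N,numeric,"total nutrient iron concentration in the medium, uM (includes 1 uM endogenous iron)"
basis,character,"data = measurement-derived value; sim = the published simulated value"
quantity,character,"alpha (hr^-1); Fe_cell, C, CIA, FM, FS, MP, F2, F3, VP (uM, compartment basis); fFe_cyt/fFe_mit/fFe_vac (uM, whole-cell basis: fractional volume times compartment concentration); R_cell, R_mit, R_vac, R_cyt_only (uM/hr; R_cyt_only = R_cyt - R_mit - R_vac)"
value,numeric,"value as printed (2 significant figures); NA when unparseable"
flag,character,"ok = algebra-validated parse; discrepant = conflicts with another printed cell; reconstructed = re-derived from compartment-sum algebra after a source-extraction defect; unparsed = excluded from all tests"
note,character,free-text provenance note
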