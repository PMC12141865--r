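antibiotic	abx_class	lead	s_min_mm	r_max_mm
piperacillin	penicillins	TRUE	20	17
piperacillin/tazobactam	penicillins	FALSE	20	17
ceftazidime	cephalosporins	TRUE	17	14
ceftazidime/avibactam	cephalosporins	FALSE	17	14
meropenem	carbapenems	TRUE	24	18
imipenem	carbapenems	FALSE	22	17
ciprofloxacin	fluoroquinolones	TRUE	26	23
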