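case_id	gene	cdna	protein	inheritance	age_years	height_sd	hc_sd	intellectual_disability	other_features
COG1744	PPP2R5D	c.592G>A	p.Glu198Lys	de_novo	0.3	2.3	3.6	Yes	Hypospadias
COG1674	PPP2R5D	c.598G>A	p.Glu200Lys	de_novo	1.7	-1.4	3.8	Yes	
COG0328	PPP2R5D	c.598G>A	p.Glu200Lys	unknown	14	2	3.8	Yes	Parkinsonism
COG0681	PPP2R5C	c.468_470delAAC	p.Thr157del	de_novo	9.3	1.6	3.3	Yes	Facial asymmetry, conductive hearing loss
COG0955	PPP2R5B	c.482C>T	p.Ser161Leu	de_novo	17.5	3	0.3	Yes	Swelling of PIPJ
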