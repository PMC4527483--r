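gene	cdna	protein
PPP2R5D	c.592G>A	p.Glu198Lys
PPP2R5D	c.598G>A	p.Glu200Lys
PPP2R5C	c.468_470delAAC	p.Thr157del
PPP2R5B	c.482C>T	p.Ser161Leu
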