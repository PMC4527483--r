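gene	name	start	end
PPP2R5B	intra-repeat loop 2	155	168
PPP2R5C	intra-repeat loop 2	151	164
PPP2R5D	intra-repeat loop 2	192	205
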