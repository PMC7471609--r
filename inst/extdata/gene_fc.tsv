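gene	log2fc
gP	0.378511623253729
gE	0.232660756790278
gA	9.96578428466205
gEch	1.20163386116965
gN	-0.473931188332413
gBif	0
gG	0
gH2	0
gMat	0
gS	0
gT	0
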