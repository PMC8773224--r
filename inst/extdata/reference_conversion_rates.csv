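construct,condition,conversion_rate_pct
CaMPARI2-F391W,Histamine,65
CaMPARI2,Histamine,55
CaMPARI2-F391W,Pre-Parabola,13
CaMPARI2,Pre-Parabola,2
CaMPARI2-F391W,Histamine+GSK2193874,39
GFP,Any,0
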