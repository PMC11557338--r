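# Y-chromosome gene panel for donor sex inference
ZFY
RPS4Y1
EIF1AY
KDM5D
NLGN4Y
TMSB4Y
UTY
DDX3Y
USP9Y
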