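condition,code,terminology
chd,G30..,read
chd,G33..,read
chd,G34..,read
heart_failure,G58..,read
heart_failure,G580.,read
heart_failure,G581.,read
pad,G73..,read
pad,G731.,read
pad,G732.,read
stroke,G61..,read
stroke,G63..,read
stroke,G64..,read
stroke,G66..,read
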