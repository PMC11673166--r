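approach,numerical_tests,categorical_tests,distance,total
Proposed,Good,Excellent,Good,Good
GM,Excellent,Excellent,Excellent,Excellent
SDV,Excellent,Excellent,Excellent,Excellent
CTGAN,Good,Excellent,Excellent,Excellent
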