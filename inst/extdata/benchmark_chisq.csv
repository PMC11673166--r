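attribute,Proposed,GM,SDV,CTGAN
Outcome,0.977744,0.9486,0.8987,0.901
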