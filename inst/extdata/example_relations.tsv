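10340919	CPR:4	Arg1:T1	Arg2:T2
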