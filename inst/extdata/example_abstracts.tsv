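10340919	Example	The effects of meloxicam were compared with those of diclofenac, a nonselective COX inhibitor.
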