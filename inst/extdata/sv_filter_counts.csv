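sample_id,n_detected,n_after_wf1,n_after_wf2
T49,553,200,35
T47,237,115,5
T30,183,96,34
T52,625,445,7
T35,89,27,1
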