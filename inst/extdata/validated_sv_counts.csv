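sample_id,duplication,insertion,deletion,translocation,inversion
T49,2,0,5,9,7
T47,0,0,0,1,0
T30,3,0,20,0,5
T52,0,1,0,1,0
T35,0,0,0,0,0
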