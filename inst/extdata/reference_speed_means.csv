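speed,lc_al,favg_al,fstep_al,si_fstep
3,0.67,1.49,2.91,1.90
7,0.95,1.82,3.97,5.21
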