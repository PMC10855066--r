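compound,ksv_absent_m1,ksv_present_m1,reduction_percent
1,33770,32240,4.5
2,7780,5020,35.5
3,16830,9390,44.2
5,15530,9240,40.5
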