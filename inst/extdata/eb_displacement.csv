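compound,ksv_m1,percent_ex
1,3350,24.72
2,3280,25.82
3,3850,27.86
4,3960,28.08
5,3410,29.06
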