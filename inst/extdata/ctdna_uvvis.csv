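compound,kapp_m1,dg_jmol,percent_h
1,2820,-19700,6.64
2,830,-16700,5.97
3,6710,-21800,7.33
4,7020,-21900,11.61
5,3060,-19900,9.92
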