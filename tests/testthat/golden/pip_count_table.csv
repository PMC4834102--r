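row,numerator,denominator,percent,ci_low,ci_high
overall_pip,52,195,26.7,20.5,32.9
pip_1,50,195,25.6,19.5,31.8
pip_2,2,195,1,0,2.4
pip_3plus,0,195,0,0,0
duplication,12,195,6.2,2.8,9.5
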