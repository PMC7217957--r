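P04233	4.489047570
Q15063	1.551003753
P51884	1.490571730
Q9NS69	1.019845999
P62841	-0.888995137
P16070	-1.624465232
P01871	-2.556118873
P18031	-3.480889810
intercept	-1.258554293
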