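mfi	abc
300	3000
1212.30930280597	12123.0930280597
4898.97948556636	48989.7948556636
19796.9280153591	197969.280153591
80000	8e+05
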