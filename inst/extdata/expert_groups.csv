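group,mean_dev_mm,sd_dev_mm
1,1.12,0.15
2,1.45,0.25
3,1.38,0.19
4,1.86,0.42
5,1.52,0.28
6,1.24,0.17
7,1.67,0.35
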