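group,age_months,vlf_ms2,lf_ms2,hf_ms2,total_ms2
healthy,2,1156.6,1378.5,5836.2,8371.3
GRMD,2,455.3,539.3,1561.7,2556.3
healthy,6,4973.7,4201.8,20172.9,29348.4
GRMD,24,6411.2,47926.1,32883.1,87220.4
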