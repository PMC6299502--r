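arm,n_total,sr_abstinent,sr_failure,survey_missing,urine_abstinent,urine_failure,urine_missing
Tx1,306,65,194,47,38,6,21
Tx2,296,59,170,67,34,6,19
Tx3,309,61,197,51,35,6,20
Tx4,306,79,156,71,50,7,22
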