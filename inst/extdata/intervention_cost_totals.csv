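arm,total_gbp
bsci,581
usual_care,96
integrated_care,963
scc_referral,412
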