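arm,comparison,role,quit_prob_12m,sd
bsci,bsci_vs_uc,intervention,0.230,0.027
usual_care,bsci_vs_uc,comparator,0.165,0.023
integrated_care,ic_vs_scc,intervention,0.155,0.017
scc_referral,ic_vs_scc,comparator,0.065,0.012
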