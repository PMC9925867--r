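arm,comparison,role,quit_prob_12m,sd
bsci,bsci_vs_uc,intervention,0.173,0.024
usual_care,bsci_vs_uc,comparator,0.119,0.020
integrated_care,ic_vs_scc,intervention,0.089,0.013
scc_referral,ic_vs_scc,comparator,0.045,0.010
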