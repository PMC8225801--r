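parameter,value,low,high,sd,distribution,provenance
p_NoBE_NDBE,0.004233,,,,beta,paper-appendix
p_NDBE_LGD,0.106778,,,,beta,paper-appendix
p_NDBE_EarlyEAC,0.001447,,,,beta,paper-appendix
p_LGD_NDBE,0.036828,,,,beta,paper-appendix
p_LGD_HGD,0.126141,,,,beta,paper-appendix
p_HGD_EarlyEAC,0.08106,,,,beta,paper-appendix
p_EarlyEAC_LateEAC,0.75,,,,beta,paper-appendix
p_mort_EarlyEAC,0.05,,,,beta,paper-appendix
p_mort_LateEAC,0.75,,,,beta,paper-appendix
success_NDBE,0.77018,0.64,0.96,,beta,paper-appendix
success_LGD,0.85,0.68,1.0,,beta,paper-appendix
success_HGD,0.85,0.68,1.0,,beta,paper-appendix
success_EarlyEAC,0.85,0.68,1.0,,beta,paper-appendix
esoph_90day_mortality,0.033,,,,beta,paper-appendix
eac_surgery_fraction,0.5,,,,beta,assumption
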