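event,decrement,duration_years,event_prob,low,high,sd,distribution,provenance
stricture,0.12,0.038462,0.08,,,0.024,beta,paper-appendix
perforation,0.15,0.076923,0.01,,,0.03,beta,paper-appendix
emr_rfa,0.12,0.076923,1.0,,,0.024,beta,paper-appendix
chemotherapy,0.15,0.375,1.0,,,0.03,beta,paper-appendix
esophagectomy,0.2,0.25,1.0,,,0.04,beta,paper-appendix
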