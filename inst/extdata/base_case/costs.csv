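parameter,value,low,high,sd,distribution,provenance
cytosponge_test,258.822249093108,144,344,,gamma,derived-calibration
endoscopy_biopsy,488,,,,gamma,paper-main-text
ppi_annual,33.54,,,,gamma,paper-appendix
endotherapy_emr,1500,,,,gamma,paper-appendix
endotherapy_rfa,6668,,,,gamma,paper-appendix
esophagectomy,11000,,,,gamma,paper-appendix
chemotherapy,9500,,,,gamma,paper-appendix
palliative_care,4000,,,,gamma,paper-appendix
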