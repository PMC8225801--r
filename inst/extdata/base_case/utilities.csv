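parameter,value,low,high,sd,distribution,provenance
NoBE,0.8041,,,0.034,beta,paper-appendix
NDBE,0.8025,,,0.033,beta,paper-appendix
LGD,0.7825,,,0.032,beta,paper-appendix
HGD,0.68,,,0.034,beta,paper-appendix
EarlyEAC,0.62,,,0.031,beta,paper-appendix
LateEAC,0.45,,,0.023,beta,paper-appendix
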