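# Toy weighting factors for the synthetic human-like phantom.  wT sums to 1
# over the four listed target tissues (a real table spans all ICRP tissues);
# wR = 1 for low-LET radiations.
kind,key,value
wT,Liver,0.3
wT,Kidneys,0.2
wT,Redmarrow,0.4
wT,Bladder,0.1
wR,beta,1
wR,photon,1
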