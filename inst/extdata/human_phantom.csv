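# Toy human-like phantom (synthetic; NOT a published reference phantom).
# Masses in grams, inclusive of regional blood.
region,mass_g,is_source,is_target
Liver,1800,TRUE,TRUE
Kidneys,310,TRUE,TRUE
Redmarrow,1170,TRUE,TRUE
Bladder,50,TRUE,TRUE
Restofbody,69670,TRUE,FALSE
TOTALBODY,73000,FALSE,FALSE
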