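# Toy mouse-like phantom (synthetic; NOT a published reference phantom).
# Masses in grams, inclusive of regional blood.  Carcass = total body minus
# the excisable regions (liver, kidneys, blood); it contains the red marrow.
region,mass_g,is_source,is_target
Liver,1.9,TRUE,TRUE
Kidneys,0.5,TRUE,TRUE
Blood,1.7,TRUE,FALSE
Redmarrow,0.22,TRUE,TRUE
Carcass,20.9,FALSE,FALSE
TOTALBODY,25,FALSE,FALSE
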