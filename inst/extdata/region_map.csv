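# Assay label -> phantom source-region mapping (explicit, no fuzzy matching).
measured_region,phantom_region
Liver,Liver
Kidneys,Kidneys
Whole blood,Blood
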