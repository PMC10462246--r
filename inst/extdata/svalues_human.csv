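# Synthetic S-value matrix for the toy human-like phantom and the
# betagamma_toy nuclide (NOT from a published S-value library).
# Beta self-dose rows equal delta_np / M(region), i.e. complete local
# absorption of the non-penetrating emissions; photon rows add self and
# cross-fire contributions of plausible magnitude.
target,source,svalue_Gy_per_Bq_s,radiation_type
Liver,Liver,1.3333333333333334e-14,beta
Kidneys,Kidneys,7.741935483870968e-14,beta
Redmarrow,Redmarrow,2.0512820512820513e-14,beta
Bladder,Bladder,4.8e-13,beta
Liver,Liver,8.0e-16,photon
Kidneys,Kidneys,2.0e-15,photon
Redmarrow,Redmarrow,9.0e-16,photon
Bladder,Bladder,6.0e-15,photon
Liver,Kidneys,2.0e-16,photon
Liver,Redmarrow,1.5e-16,photon
Liver,Bladder,4.0e-17,photon
Kidneys,Liver,2.0e-16,photon
Kidneys,Redmarrow,2.0e-16,photon
Kidneys,Bladder,8.0e-17,photon
Redmarrow,Liver,1.5e-16,photon
Redmarrow,Kidneys,2.0e-16,photon
Redmarrow,Bladder,7.0e-17,photon
Bladder,Liver,4.0e-17,photon
Bladder,Kidneys,8.0e-17,photon
Bladder,Redmarrow,7.0e-17,photon
Liver,Restofbody,1.2e-16,photon
Kidneys,Restofbody,1.2e-16,photon
Redmarrow,Restofbody,1.2e-16,photon
Bladder,Restofbody,1.2e-16,photon
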