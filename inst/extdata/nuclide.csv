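# Synthetic beta/gamma emitter loosely resembling a therapeutic lanthanide.
# delta_np_J: mean non-penetrating (beta + conversion electron) energy per
# decay in joules.  dose_fraction partitions the absorbed dose by radiation
# type for equivalent/RBE weighting.
name,half_life_h,delta_np_J,radiation_type,dose_fraction
betagamma_toy,159.5,2.4e-14,beta,0.85
betagamma_toy,159.5,2.4e-14,photon,0.15
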