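# Example marker-set configuration: functional marker -> member HMM profiles.
# combine_rule "any": a genome is positive if any member profile hits.
name	hmm_ids	combine_rule
alkB	alkB	any
ladA_alpha	ladA_alpha	any
naphthalene_dioxygenase	nahAc,ndoB	any
monoaromatic_aerobic	todC1,xylM	any
alkane_anaerobic	assA	any
monoaromatic_anaerobic	bssA	any
polyaromatic_anaerobic	ncr	any
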