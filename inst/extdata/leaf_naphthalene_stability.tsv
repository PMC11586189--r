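# Naphthalene concentrations (ng cm^-2, mean of two NaClO-treated ivy plants)
# measured on leaf surfaces over 96 h to assess abiotic loss.
time_h	concentration_ng_cm2
0	10.9
6	11.9
24	13.6
48	10.3
96	11.0
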