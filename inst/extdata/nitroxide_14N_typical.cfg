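# Typical nitroxide (proxyl/MTSSL-class) magnetic parameters at X band.
# These are representative literature values, not measurements of any
# specific sample; replace with your own tensors for quantitative work.
nuclear_spin 1
g_principal 2.0083 2.0061 2.0022
a_principal 17.4 17.4 98.0
a_unit MHz
mw_frequency_ghz 9.45
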