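# Typical 15N-enriched nitroxide parameters (14N tensor scaled by the
# gyromagnetic ratio magnitude |gamma15/gamma14| = 1.4027). Representative
# values only; supply a measured 15N tensor for quantitative work.
nuclear_spin 0.5
g_principal 2.0083 2.0061 2.0022
a_principal 24.4 24.4 137.5
a_unit MHz
mw_frequency_ghz 9.45
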