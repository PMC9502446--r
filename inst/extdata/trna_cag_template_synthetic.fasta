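>synthetic_tRNA_CAG_template constructed 76-nt cloverleaf; CAG anticodon at 34-36 (1-based); carries G33, GGG/CCC in the TpsiC window, discriminator G73, terminal CCA; not a natural tRNA sequence
GCCGAUUUAGCUCAGUUGGUAGAGCAGGAUUCGCAGAAAAUCCAGUCUGGGUUCGAAUCC
CAGUUCGAGUCUGCCA
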