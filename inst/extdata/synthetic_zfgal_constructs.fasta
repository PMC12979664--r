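>zfGal_IDR_synthetic synthetic stand-in for a tryptophan-rich zebrafish galectin IDR (six W-tetrapeptides, each repeated)
MADFSPSQGWPGQPTSGQPWAPGAGQGPSWGSPQQGSSTTWQPAGSAAATQWSGAGAAAP
WPASAGQGPAWPGQSSQQQSTWAPGTGTSPTWGSPAAPQQWQPAPAQASTSWSGATSPGG
AWPASAPTTGSA
>zfGal_aug_IDR_synthetic synthetic augmented construct: the six W-tetrapeptides duplicated once each
MADFSPSQGWPGQWPGQPTSGQPWAPGWAPGAGQGPSWGSPWGSPQQGSSTTWQPAWQPA
GSAAATQWSGAWSGAGAAAPWPASWPASAGQGPAWPGQSSQQQSTWAPGTGTSPTWGSPA
APQQWQPAPAQASTSWSGATSPGGAWPASAPTTGSA
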