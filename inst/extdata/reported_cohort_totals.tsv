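quantity	value
n_variants	68779
n_disease	24399
n_polymorphism	37878
n_unclassified	6502
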