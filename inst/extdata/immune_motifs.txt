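# Immune-stimulatory sequence motifs screened on both siRNA strands.
# One motif per line; edit to extend the screen.
UGUGU
GUCCUUCA
CUGAAUU
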