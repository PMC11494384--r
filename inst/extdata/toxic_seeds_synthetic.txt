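# Toxic-seed blacklist (guide positions 2-8, one 7-mer per line).
# This file ships EMPTY on purpose: no published consensus list is bundled.
# Add your own entries, e.g.
#   GGGGGCC
# and load with load_seed_blacklist().
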