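# RNA/RNA Watson-Crick nearest-neighbor free energies, delta-G at 37 C (kcal/mol)
# Source: Xia et al. (1998) Biochemistry 37:14719-14735 (Turner rules).
# Stacks are keyed by the top-strand dinucleotide 5'->3'; the table is
# symmetric under reverse complement. version=xia1998-v1
entry	value
init	4.09
terminal_au	0.45
AA	-0.93
AC	-2.24
AG	-2.08
AU	-1.10
CA	-2.11
CC	-3.26
CG	-2.36
CU	-2.08
GA	-2.35
GC	-3.42
GG	-3.26
GU	-2.24
UA	-1.33
UC	-2.35
UG	-2.11
UU	-0.93
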