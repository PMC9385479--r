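# Nearest-neighbour free-energy increments for Watson-Crick RNA/RNA helices
# at 37 degrees C (kcal/mol), INN-HB parameter set (Xia et al. 1998).
# step: top-strand dinucleotide 5'->3'; the bottom strand is its complement.
# Special terms: init (helix initiation), term_au (per terminal A-U pair),
# symmetry (self-complementary duplex correction).
step	dg37_kcal_mol
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
init	4.09
term_au	0.45
symmetry	0.43
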