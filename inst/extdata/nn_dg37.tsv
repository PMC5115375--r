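# Watson-Crick nearest-neighbor stack free energies, dG at 37 C, kcal/mol.
# Values follow the unified oligonucleotide parameter set (SantaLucia & Hicks,
# Annu. Rev. Biophys. Biomol. Struct. 2004). Stack key is the top-strand
# dinucleotide read 5'->3'; the bottom strand is its Watson-Crick complement.
# Hairpin loop penalties (loop_<n>, n = loop length in nt) are on the same
# scale, lightly smoothed to be monotone non-decreasing; constant beyond 30.
# Scalar penalties: duplex initiation, and flat per-mismatch destabilization
# (internal / terminal) used in place of full mismatch tables.
AA	-1.00
AC	-1.44
AG	-1.28
AT	-0.88
CA	-1.45
CC	-1.84
CG	-2.17
CT	-1.28
GA	-1.30
GC	-2.24
GG	-1.84
GT	-1.44
TA	-0.58
TC	-1.30
TG	-1.45
TT	-1.00
initiation	1.96
mismatch_internal	1.50
mismatch_terminal	0.75
loop_3	3.50
loop_4	3.60
loop_5	3.70
loop_6	4.00
loop_7	4.20
loop_8	4.30
loop_9	4.40
loop_10	4.50
loop_11	4.60
loop_12	4.70
loop_13	4.80
loop_14	4.90
loop_15	4.95
loop_16	5.00
loop_17	5.10
loop_18	5.20
loop_19	5.25
loop_20	5.30
loop_21	5.37
loop_22	5.43
loop_23	5.49
loop_24	5.55
loop_25	5.60
loop_26	5.66
loop_27	5.72
loop_28	5.78
loop_29	5.84
loop_30	5.90
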