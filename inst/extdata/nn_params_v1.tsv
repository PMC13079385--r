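# rnapal nearest-neighbor RNA free-energy parameters, version 1.0
# Turner 2004 free energies at 37 C, kcal/mol.
# Schema: section<TAB>key1<TAB>key2<TAB>value
#  scalar rows: key1 = parameter name, key2 = '.'
#  stack rows: key1 = top dimer (bases i,i+1, 5'->3'), key2 = bottom
#    dimer (bases j-1,j, 5'->3'); pairs are (i,j) and (i+1,j-1).
#  loop rows (hairpin/bulge/internal): key1 = loop size in unpaired nt.
section	key1	key2	value
scalar	temperature	.	310.15
scalar	duplex_init	.	4.1
scalar	terminal_au	.	0.5
scalar	symmetry_correction	.	0.43
scalar	lxc	.	1.07856
scalar	min_hairpin	.	3
scalar	max_interior_loop	.	30
stack	CC	GG	-3.30
stack	CG	CG	-2.40
stack	CG	UG	-1.40
stack	CU	GG	-2.10
stack	CA	UG	-2.10
stack	CU	AG	-2.10
stack	GC	GC	-3.40
stack	GG	CC	-3.30
stack	GG	UC	-1.50
stack	GU	GC	-2.50
stack	GA	UC	-2.40
stack	GU	AC	-2.20
stack	GC	GU	-2.50
stack	GG	CU	-2.10
stack	GG	UU	-0.50
stack	GU	GU	1.30
stack	GA	UU	-1.30
stack	GU	AU	-1.40
stack	UC	GG	-1.50
stack	UG	CG	-1.40
stack	UG	UG	0.30
stack	UU	GG	-0.50
stack	UA	UG	-1.00
stack	UU	AG	-0.60
stack	AC	GU	-2.20
stack	AG	CU	-2.10
stack	AG	UU	-0.60
stack	AU	GU	-1.40
stack	AA	UU	-0.90
stack	AU	AU	-1.10
stack	UC	GA	-2.40
stack	UG	CA	-2.10
stack	UG	UA	-1.00
stack	UU	GA	-1.30
stack	UA	UA	-1.30
stack	UU	AA	-0.90
hairpin	3	.	5.40
hairpin	4	.	5.60
hairpin	5	.	5.70
hairpin	6	.	5.40
hairpin	7	.	6.00
hairpin	8	.	5.50
hairpin	9	.	6.40
hairpin	10	.	6.50
hairpin	11	.	6.60
hairpin	12	.	6.70
hairpin	13	.	6.80
hairpin	14	.	6.90
hairpin	15	.	6.90
hairpin	16	.	7.00
hairpin	17	.	7.10
hairpin	18	.	7.10
hairpin	19	.	7.20
hairpin	20	.	7.20
hairpin	21	.	7.30
hairpin	22	.	7.30
hairpin	23	.	7.40
hairpin	24	.	7.40
hairpin	25	.	7.50
hairpin	26	.	7.50
hairpin	27	.	7.50
hairpin	28	.	7.60
hairpin	29	.	7.60
hairpin	30	.	7.70
bulge	1	.	3.80
bulge	2	.	2.80
bulge	3	.	3.20
bulge	4	.	3.60
bulge	5	.	4.00
bulge	6	.	4.40
bulge	7	.	4.60
bulge	8	.	4.70
bulge	9	.	4.80
bulge	10	.	4.90
bulge	11	.	5.00
bulge	12	.	5.10
bulge	13	.	5.20
bulge	14	.	5.30
bulge	15	.	5.40
bulge	16	.	5.40
bulge	17	.	5.50
bulge	18	.	5.50
bulge	19	.	5.60
bulge	20	.	5.70
bulge	21	.	5.70
bulge	22	.	5.80
bulge	23	.	5.80
bulge	24	.	5.80
bulge	25	.	5.90
bulge	26	.	5.90
bulge	27	.	6.00
bulge	28	.	6.00
bulge	29	.	6.00
bulge	30	.	6.10
internal	2	.	1.00
internal	3	.	1.00
internal	4	.	1.10
internal	5	.	2.00
internal	6	.	2.00
internal	7	.	2.10
internal	8	.	2.30
internal	9	.	2.40
internal	10	.	2.50
internal	11	.	2.60
internal	12	.	2.70
internal	13	.	2.80
internal	14	.	2.90
internal	15	.	2.90
internal	16	.	3.00
internal	17	.	3.10
internal	18	.	3.10
internal	19	.	3.20
internal	20	.	3.30
internal	21	.	3.30
internal	22	.	3.40
internal	23	.	3.40
internal	24	.	3.50
internal	25	.	3.50
internal	26	.	3.50
internal	27	.	3.60
internal	28	.	3.60
internal	29	.	3.70
internal	30	.	3.70
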