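type	resname	atom1	atom2	edge	adj1	edge1	adj2	edge2
pair	A	N1	N6	WC	.	.	.	.
pair	A	N6	N7	HG	.	.	.	.
pair	A	N3	N9	SG	.	.	.	.
pair	A	N3	O2'	SG	.	.	.	.
pair	G	N1	N2	WC	.	.	.	.
pair	G	N1	O6	WC	.	.	.	.
pair	G	N7	O6	HG	.	.	.	.
pair	G	N2	N3	SG	.	.	.	.
pair	G	N3	N9	SG	.	.	.	.
pair	G	N3	O2'	SG	.	.	.	.
pair	C	N3	N4	WC	.	.	.	.
pair	C	N3	O2	WC	.	.	.	.
pair	C	N1	O2	SG	.	.	.	.
pair	C	O2	O2'	SG	.	.	.	.
pair	U	N3	O2	WC	.	.	.	.
pair	U	N3	O4	WC	.	.	.	.
pair	U	N1	O2	SG	.	.	.	.
pair	U	O2	O2'	SG	.	.	.	.
single	A	N1	.	WC	.	.	.	.
single	A	N3	.	SG	.	.	.	.
single	A	N7	.	HG	.	.	.	.
single	G	N1	.	WC	.	.	.	.
single	G	N3	.	SG	.	.	.	.
single	G	N7	.	HG	.	.	.	.
single	C	N3	.	WC	.	.	.	.
single	C	N4	.	WC	.	.	.	.
single	U	N3	.	WC	.	.	.	.
single	U	O4	.	WC	.	.	.	.
ambiguous	A	N6	.	.	N1	WC	C5	HG
ambiguous	G	O6	.	.	N1	WC	C5	HG
ambiguous	G	N2	.	.	N1	WC	N3	SG
ambiguous	C	O2	.	.	N3	WC	N1	SG
ambiguous	U	O2	.	.	N3	WC	N1	SG
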