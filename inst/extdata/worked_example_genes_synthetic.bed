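chr4	122449999	122480000	ANXA5	0	.
chr4	122519999	122540000	TMEM155	0	.
chr4	122699999	122740000	EXOSC9	0	.
chr4	122744999	122790000	BBS7	0	.
chr4	122799999	122870000	TRPC3	0	.
chr4	122899999	123150000	KIAA1109	0	.
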