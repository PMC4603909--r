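genome_id	n_tcs	n_hk	n_hybrid	n_pp	n_rr	pct_hybrid	pct_tm_hk	pct_orphan	pct_paired	pct_complex	n_intricate_foci	complete
Mx	282	103	37	5	137	26.4	47	35	35	30	8	TRUE
Mf	288	98	49	3	138	33.3	41	34	33	33	9	TRUE
Cc	306	106	56	2	142	34.6	38	34	35	31	8	TRUE
Sa	338	124	70	4	142	36.1	40	34	34	32	9	TRUE
AdC	188	68	17	1	102	20.2	48	43	35	22	2	TRUE
Ad1	187	69	19	1	98	21.6	50	40	34	26	2	TRUE
AF	207	72	35	0	100	33.3	50	28	33	39	5	TRUE
AK	191	72	18	0	101	20.0	49	41	35	24	2	TRUE
Sc	273	101	50	1	121	33.1	41	37	27	37	9	TRUE
Ca	301	109	50	2	140	31.4	45	.	.	.	.	FALSE
Ho	191	53	51	3	84	49.0	35	35	38	27	5	TRUE
Pp	160	60	26	5	69	30.2	42	.	.	.	.	FALSE
Bb	92	32	16	2	42	33.3	73	37	48	18	4	TRUE
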