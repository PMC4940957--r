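# Fickett (1982) TESTCODE lookup tables, transcribed from the original
# publication (as also used by coding-potential assessment tools). For each
# base, the position-asymmetry parameter max(c1,c2,c3)/(min(c1,c2,c3)+1) and
# the content fraction are converted to probabilities via these tables: the
# probability of the first row whose threshold the parameter value reaches
# (rows ordered by descending threshold) is taken, then weighted and summed
# over the eight terms.
kind	base	threshold	prob	weight
position	A	1.9	0.94	0.26
position	A	1.8	0.68	0.26
position	A	1.7	0.84	0.26
position	A	1.6	0.93	0.26
position	A	1.5	0.58	0.26
position	A	1.4	0.68	0.26
position	A	1.3	0.45	0.26
position	A	1.2	0.34	0.26
position	A	1.1	0.20	0.26
position	A	0.0	0.22	0.26
position	C	1.9	0.80	0.18
position	C	1.8	0.70	0.18
position	C	1.7	0.70	0.18
position	C	1.6	0.81	0.18
position	C	1.5	0.66	0.18
position	C	1.4	0.48	0.18
position	C	1.3	0.51	0.18
position	C	1.2	0.33	0.18
position	C	1.1	0.30	0.18
position	C	0.0	0.23	0.18
position	G	1.9	0.90	0.31
position	G	1.8	0.88	0.31
position	G	1.7	0.74	0.31
position	G	1.6	0.64	0.31
position	G	1.5	0.53	0.31
position	G	1.4	0.48	0.31
position	G	1.3	0.27	0.31
position	G	1.2	0.16	0.31
position	G	1.1	0.08	0.31
position	G	0.0	0.08	0.31
position	T	1.9	0.97	0.33
position	T	1.8	0.97	0.33
position	T	1.7	0.91	0.33
position	T	1.6	0.68	0.33
position	T	1.5	0.69	0.33
position	T	1.4	0.44	0.33
position	T	1.3	0.54	0.33
position	T	1.2	0.20	0.33
position	T	1.1	0.09	0.33
position	T	0.0	0.09	0.33
content	A	0.33	0.28	0.11
content	A	0.31	0.49	0.11
content	A	0.29	0.44	0.11
content	A	0.27	0.55	0.11
content	A	0.25	0.62	0.11
content	A	0.23	0.49	0.11
content	A	0.21	0.67	0.11
content	A	0.19	0.65	0.11
content	A	0.17	0.81	0.11
content	A	0.00	0.21	0.11
content	C	0.33	0.82	0.12
content	C	0.31	0.64	0.12
content	C	0.29	0.51	0.12
content	C	0.27	0.64	0.12
content	C	0.25	0.59	0.12
content	C	0.23	0.59	0.12
content	C	0.21	0.58	0.12
content	C	0.19	0.44	0.12
content	C	0.17	0.51	0.12
content	C	0.00	0.58	0.12
content	G	0.33	0.40	0.15
content	G	0.31	0.54	0.15
content	G	0.29	0.47	0.15
content	G	0.27	0.64	0.15
content	G	0.25	0.64	0.15
content	G	0.23	0.73	0.15
content	G	0.21	0.41	0.15
content	G	0.19	0.41	0.15
content	G	0.17	0.33	0.15
content	G	0.00	0.29	0.15
content	T	0.33	0.28	0.14
content	T	0.31	0.24	0.14
content	T	0.29	0.39	0.14
content	T	0.27	0.40	0.14
content	T	0.25	0.55	0.14
content	T	0.23	0.75	0.14
content	T	0.21	0.56	0.14
content	T	0.19	0.69	0.14
content	T	0.17	0.51	0.14
content	T	0.00	0.58	0.14
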