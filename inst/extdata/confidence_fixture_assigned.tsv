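method	module_id	tier	n	n_ex	ex_mean	cor_mean	mf_mean	bp_mean	cc_mean
CFINDER	Int-2	High	5	5	8.33	0.22	0.76	0.7	0.7
CFINDER	Int-3	High	5	1	8.54	NA	0.85	0.88	0.84
CFINDER	Int-4	High	9	7	9.56	0.43	0.7	0.81	0.92
CFINDER	Int-7	High	17	13	8.88	0.17	0.63	0.58	0.66
CFINDER	Lit-2	High	5	5	8.33	0.22	0.76	0.7	0.7
CFINDER	Lit-5	High	9	9	9.62	0.42	0.59	0.68	0.66
CFINDER	Lit-9	High	8	8	9.02	0.62	0.85	0.92	0.82
CFINDER	Lit-11	High	10	9	8.17	0.3	0.58	0.74	0.61
CFINDER	Ortho-8	High	15	11	8.9	0.15	0.68	0.57	0.67
CFINDER	Ortho-12	High	10	9	10.73	0.59	0.83	1	0.98
CFINDER	Int-18	Medium	18	16	9.55	0.54	0.45	0.51	0.7
CFINDER	Ortho-18	Medium	17	15	9.65	0.58	0.49	0.6	0.72
CFINDER	Int-13	Low	13	11	8.79	0.39	0.45	0.73	0.96
CFINDER	Lit-4	Low	16	11	7.95	0.24	0.28	0.52	0.58
CFINDER	Lit-14	Low	11	10	8.79	0.39	0.4	0.72	0.95
CFINDER	Ortho-7	Low	8	7	9.48	0.41	0.48	0.56	0.61
MCODE	Int-5	High	9	7	9.56	0.43	0.7	0.81	0.92
MCODE	Lit-4	High	7	7	8.99	0.13	0.89	0.79	0.71
MCODE	Ortho-4	High	12	9	9.37	0.31	0.51	0.59	0.54
MCODE	Ortho-5	High	9	7	12.92	0.77	0.65	0.78	0.71
MCODE	Lit-11	Low	9	8	8.34	0.24	0.4	0.59	0.69
MCODE	Lit-13	Low	22	20	8.81	0.32	0.33	0.5	0.63
MCODE	Ortho-2	Low	6	5	8.08	0.29	0.41	0.78	0.73
MCODE	Ortho-10	Low	11	9	8.38	0.38	0.39	0.52	0.67
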