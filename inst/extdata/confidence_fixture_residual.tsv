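method	module_id	n	n_ex	ex_mean	cor_mean	mf_mean	bp_mean	cc_mean
CFINDER	Int-1	1496	1348	8.73	0.13	NA	NA	NA
CFINDER	Int-5	7	4	10.71	0.57	0.31	0.35	0.42
CFINDER	Int-6	8	5	8.39	0.39	0.34	0.32	0.54
CFINDER	Int-8	8	8	9.5	0.44	0.5	0.46	0.62
CFINDER	Int-9	8	6	8.68	0.49	0.27	0.46	0.81
CFINDER	Int-10	12	10	8.64	0.41	0.39	0.49	0.61
CFINDER	Int-11	9	9	9.08	0.41	0.42	0.26	0.64
CFINDER	Int-12	11	10	8.84	0.26	0.35	0.36	0.5
CFINDER	Int-14	14	9	8.76	0.4	0.37	0.2	0.67
CFINDER	Int-15	15	9	8.42	0.46	0.55	0.23	0.8
CFINDER	Int-16	14	8	8.42	0.46	0.43	0.21	0.76
CFINDER	Int-17	28	13	12.06	0.6	0.46	0.56	0.49
CFINDER	Int-19	21	9	10.03	0.28	0.4	0.48	0.47
CFINDER	Int-20	18	6	9.07	0.36	0.47	0.34	0.59
CFINDER	Int-21	22	10	9.5	0.12	0.39	0.48	0.47
CFINDER	Lit-1	1141	1081	8.6	0.12	NA	NA	NA
CFINDER	Lit-3	6	6	9.37	0.15	0.69	0.15	0.37
CFINDER	Lit-6	6	6	8.21	0.63	0.55	0.44	0.56
CFINDER	Lit-7	8	5	8.39	0.39	0.34	0.32	0.54
CFINDER	Lit-8	7	5	8.14	0.18	0.76	0.19	0.42
CFINDER	Lit-10	10	10	9.32	0.46	0.35	0.15	0.77
CFINDER	Lit-12	9	9	8.64	0.11	0.22	0.27	0.38
CFINDER	Lit-13	11	10	8.84	0.26	0.35	0.36	0.5
CFINDER	Ortho-1	7	2	8.6	0.5	0.41	0.19	0.57
CFINDER	Ortho-2	4	3	8.34	0.37	0.62	0.22	0.55
CFINDER	Ortho-3	4	3	8.58	-0.18	0.54	0.35	0.7
CFINDER	Ortho-4	4	4	8.65	0.69	0.44	0.45	0.48
CFINDER	Ortho-5	14	10	8.86	0.1	0.34	0.24	0.39
CFINDER	Ortho-6	7	4	10.71	0.57	0.31	0.35	0.42
CFINDER	Ortho-9	8	8	9.5	0.44	0.5	0.46	0.62
CFINDER	Ortho-10	8	6	8.68	0.49	0.27	0.46	0.81
CFINDER	Ortho-11	12	10	8.64	0.41	0.39	0.49	0.61
CFINDER	Ortho-13	58	29	10.81	0.42	0.38	0.47	0.47
CFINDER	Ortho-14	24	7	9.21	0.39	0.45	0.43	0.61
CFINDER	Ortho-15	14	9	8.76	0.4	0.37	0.2	0.67
CFINDER	Ortho-16	39	22	10.67	0.35	0.43	0.49	0.49
CFINDER	Ortho-17	15	9	8.42	0.46	0.55	0.23	0.8
CFINDER	Ortho-19	21	9	10.03	0.28	0.4	0.48	0.47
CFINDER	Ortho-20	18	6	9.07	0.36	0.47	0.34	0.59
CFINDER	Ortho-21	22	10	9.5	0.12	0.39	0.48	0.47
CFINDER	HTP-1	5	5	12.73	0.21	0.55	0.2	0.56
CFINDER	HTP-2	3	3	7.79	0.06	0.78	0.24	0.39
CFINDER	HTP-3	3	2	7.33	0.07	0.46	0.1	1
CFINDER	HTP-4	145	108	8.33	0.06	NA	NA	NA
CFINDER	HTP-5	3	2	7.97	0.05	0.44	0.05	0.29
CFINDER	HTP-6	163	120	8.99	0.15	NA	NA	NA
CFINDER	HTP-7	44	36	8.96	0.16	0.34	0.17	0.44
CFINDER	HTP-8	7	5	8.38	-0.06	0.31	0.12	0.31
CFINDER	HTP-9	5	5	9.16	0.03	0.78	0.36	0.66
MCODE	Int-1	14	13	7.37	0.1	0.49	0.44	0.5
MCODE	Int-2	9	7	7.83	-0.02	0.27	0.24	0.52
MCODE	Int-3	13	9	8.66	0.33	0.47	0.41	0.66
MCODE	Int-4	13	12	8.29	0.06	0.4	0.44	0.58
MCODE	Int-6	75	68	8.46	0.2	0.24	0.18	0.4
MCODE	Int-7	58	43	8.3	0.19	0.26	0.16	0.38
MCODE	Int-8	47	39	9.1	0.23	0.25	0.17	0.44
MCODE	Int-9	74	70	9.44	0.28	0.27	0.24	0.43
MCODE	Int-10	10	6	10.28	0.77	0.65	0.43	0.77
MCODE	Int-11	29	27	9.12	0.4	0.36	0.33	0.63
MCODE	Int-12	32	28	8.72	0.35	0.31	0.41	0.61
MCODE	Int-13	79	46	9.99	0.49	0.36	0.31	0.48
MCODE	Int-14	29	12	9.77	0.23	0.37	0.44	0.43
MCODE	Lit-1	5	5	7.87	0.02	0.53	0.06	0.46
MCODE	Lit-2	7	7	8.47	-0.01	0.44	0.32	0.74
MCODE	Lit-3	145	139	8.42	0.06	0.25	0.15	0.35
MCODE	Lit-5	5	2	8.69	0.16	0.3	0.16	0.61
MCODE	Lit-6	144	140	8.69	0.1	0.26	0.19	0.41
MCODE	Lit-7	21	21	7.98	0.05	0.33	0.19	0.39
MCODE	Lit-8	98	96	8.72	0.16	0.24	0.24	0.41
MCODE	Lit-9	15	15	8.67	0.15	0.26	0.2	0.45
MCODE	Lit-10	128	122	8.62	0.21	0.28	0.16	0.42
MCODE	Lit-12	40	39	8.79	0.23	0.29	0.28	0.51
MCODE	Ortho-1	6	3	11.12	0.67	0.32	0.37	0.39
MCODE	Ortho-3	12	8	8.65	0.32	0.45	0.37	0.66
MCODE	Ortho-6	13	6	8.38	0.24	0.28	0.2	0.53
MCODE	Ortho-7	10	10	9.16	0.12	0.44	0.21	0.68
MCODE	Ortho-8	23	20	10.08	0.51	0.35	0.33	0.56
MCODE	Ortho-9	10	6	10.28	0.77	0.65	0.43	0.77
MCODE	Ortho-11	44	31	10.58	0.53	0.35	0.43	0.48
MCODE	Ortho-12	35	15	8.81	0.45	0.44	0.28	0.64
MCODE	Ortho-13	35	15	8.81	0.45	0.44	0.28	0.64
MCODE	Ortho-14	29	12	9.77	0.23	0.37	0.44	0.43
MCODE	HTP-1	67	56	8.74	0.12	0.3	0.16	0.41
MCODE	HTP-2	17	15	9.23	0.17	0.45	0.16	0.44
MCODE	HTP-3	20	18	9.06	0.08	0.45	0.28	0.5
MCODE	HTP-4	17	15	8.83	0.14	0.38	0.16	0.37
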