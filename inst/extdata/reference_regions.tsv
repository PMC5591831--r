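modality	region	x_mm	y_mm	z_mm	r1_gamma_mean	r1_gamma_sd	r2_gamma_mean	r2_gamma_sd	cohens_d	effect_size	p_value
eeg	P4	41	-55	37	1.81	0.27	2.03	0.21	0.91	0.41	0.004
eeg	FC5	-56	1	21	1.26	0.31	1.71	0.42	1.22	0.52	0.002
fmri	Right inferior cerebellum	18	-81	-33	1.43	0.32	1.69	0.23	0.93	0.42	0.003
fmri	Left anterior insula	-36	18	2	1.37	0.36	1.63	0.24	0.84	0.39	0.004
fmri	Right medial frontal	0	15	45	1.42	0.24	1.7	0.34	0.95	0.43	0.005
fmri	Right ventral frontal	51	23	8	1.31	0.34	1.58	0.22	0.94	0.42	0.001
fmri	Left dorso-lateral prefrontal	-44	27	33	1.38	0.23	1.73	0.21	1.58	0.62	2.26e-06
fmri	Right Inferior parietal lobule	54	-44	43	1.3	0.28	1.69	0.15	1.73	0.65	6.22e-05
fmri	Left parietal	-55	-22	38	1.26	0.28	1.63	0.19	1.54	0.61	0.001
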