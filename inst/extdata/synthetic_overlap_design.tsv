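study_k	study_l	n0_shared_controls	n1_shared_cases	k_controls	k_cases	l_controls	l_cases
asthma_syn	eczema_syn	310000	1200	319207	41934	351820	9321
asthma_syn	glaucoma_syn	100000	350	319207	41934	112798	5092
asthma_syn	ibs_syn	315000	900	319207	41934	352604	8537
eczema_syn	glaucoma_syn	105000	120	351820	9321	112798	5092
eczema_syn	ibs_syn	340000	400	351820	9321	352604	8537
glaucoma_syn	ibs_syn	108000	150	112798	5092	352604	8537
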