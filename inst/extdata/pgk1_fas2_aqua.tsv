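protein	peptide	s_acp	ratio	s0_published	degree_published
Pgk1	AAGFLLEK(ac)ELK	0.023	80.8	0.0003	0.02
Pgk1	AGAEIVPK(ac)LMEK	0.095	41.5	0.0023	0.09
Pgk1	FAAGTK(ac)ALLDEVVK	0.119	27.7	0.0043	0.11
Fas2	QVLDVDPVYKDVA(ac)PTGPK	0.032	108.3	0.0003	0.03
Fas2	LIEPELFNGYNPE(ac)K	0.092	33.5	0.0027	0.09
Fas2	GATLYIP(ac)ALR	0.068	11.3	0.0060	0.06
Fas2	SEGNPVIGVFQ(ac)FLTGHPK	0.016	5.3	0.0031	0.01
Fas2	AND(ac)NESATINEMMK	0.181	1.7	0.1055	0.08
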