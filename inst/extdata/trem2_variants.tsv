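variant	site_class	provenance	kd_apoe4	kd_apoe4_se	kd_c1q	kd_c1q_se	kd_il34	kd_il34_se	fold_apoe4_printed	fold_il34_printed
WT	WT	previous-publication	281	43	0.65	0.03	16.5	0.2	-	-
R47H	basic	previous-publication	643	91	0.18	0.01	79.8	2.4	down 2.29	down 4.8
R62H	basic	previous-publication	561	117	1.66	0.06	75		down 2.00	down 4.5
D87N	AD-risk	this-paper	25	6			28.4	0.5	down 11.24	down 1.7
T96K	AD-risk	previous-publication	891	196	No binding		23.7	0.4	down 3.17	down 1.4
M41D	hydrophobic	previous-publication	1426	566	2.54	0.52			down 5.07
W44D	hydrophobic	previous-publication	2565	710					down 9.12
L69D	hydrophobic	previous-publication	55060	20390	Decreased binding				down 195.94
W70D	hydrophobic	previous-publication	28110	14380	Decreased binding				down 100.04
L71D	hydrophobic	this-paper			0.058	0.002
F74D	hydrophobic	previous-publication	9709	1163	0.11	0.01			down 34.55
L89D	hydrophobic	this-paper			Decreased binding
L69D/L71D	hydrophobic	this-paper	N.B.D.		Binding (not fit)		20.2	0.3		down 1.2
W44D/L69D/L71D	hydrophobic	this-paper	N.B.D.		Binding (not fit)		25.8	0.3		down 1.6
R46A	basic	this-paper			No Binding
R46D	basic	this-paper			No Binding		18.0	0.3		down 1.1
R46A/R47A	basic	this-paper	388	141	No Binding				down 1.38
R76D	basic	this-paper	1529	693	13.8	4.86	N.B.D		down 5.44
R77D	basic	this-paper	1659	379	No Binding		114	4	down 5.90	down 6.9
W78D	basic	this-paper					17.2	0.4		down 1.04
L75D	basic-adjacent	this-paper			0.11	0.01	36.6	0.9		down 2.2
T85D	basic-adjacent	this-paper			0.11	0.01	21.5	0.6		down 1.3
R122E	site2	this-paper					29.4	0.4		down 1.8
R122D/K123D	site2	this-paper	120	22	0.82	0.04	18.5	0.3	up 2.30	down 1.1
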