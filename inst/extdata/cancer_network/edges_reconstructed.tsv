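source	target	strength
Carcinogens	DNA_damage	1
GFs	Egfr	1
Nutrients	mTor	1
Nutrients	AMP/ATP	-1
TNFalpha	Tnfr	1
Hypoxia	Phd	-1
Hypoxia	Vhl	-1
DNA_damage	Atm/Atr	1
Atm/Atr	Chk1/2	1
Atm/Atr	p53	1
Atm/Atr	Mdm2	-1
Chk1/2	p21	1
Chk1/2	p27	1
Egfr	Grb2/Sos	1
Egfr	Pi3k	1
Egfr	Plcg	1
Grb2/Sos	Ras	1
Ras	Raf	1
Ras	Pi3k	1
Ras	p14ARF	1
Nf1	Ras	-1
Raf	Mek	1
Mek	Erk	1
Erk	Myc	1
Erk	CyclinD	1
Erk	Gsk-3	-1
Erk	Tsc1/2	-1
Erk	Bad	-1
Erk	Rb	-1
Plcg	Pkc	1
Pkc	Raf	1
Pkc	Gsk-3	-1
Pkc	Nf-kB	1
Pi3k	Pip3	1
Pten	Pip3	-1
Pip3	Pdk1	1
Pip3	Akt	1
Pdk1	Akt	1
Akt	Gsk-3	-1
Akt	Tsc1/2	-1
Akt	Bad	-1
Akt	Mdm2	1
Akt	Foxo	-1
Akt	Casp9	-1
Akt	p27	-1
Akt	p21	-1
Akt	Ikk	1
Akt	Rb	-1
Akt	hTert	1
Foxo	Hif1	-1
Foxo	p27	1
Tsc1/2	Rheb	-1
Rheb	mTor	1
mTor	Hif1	1
mTor	eIf4e	1
mTor	eEf2k	-1
eEf2k	eEf2	-1
eIf4e	Hif1	1
AMP/ATP	Ampk	1
Ampk	Tsc1/2	1
Ampk	mTor	-1
Ampk	p53	1
Ampk	Puma	1
Ampk	Bcl-2	-1
Phd	Hif1	-1
Vhl	Hif1	-2
Hif1	Glut1	1
Hif1	Ldha	1
Hif1	Vegf	1
Hif1	Myc	-1
Hypoxia	p53	1
Hif1	p27	1
Hif1	hTert	1
Hif1	E-cadherin	-1
Wnt	Dsh	1
Dsh	Gsk-3/Apc	-1
Dsh	Gsk-3	-1
Gsk-3	Gsk-3/Apc	1
Gsk-3	CyclinD	-2
Gsk-3	Snail	-1
Apc	Gsk-3/Apc	1
Gsk-3/Apc	beta-catenin	-1
beta-catenin	Tcf	1
beta-catenin	hTert	1
Tcf	Myc	1
Tcf	CyclinD	1
Snail	Slug	1
Snail	E-cadherin	-1
Snail	Bcl-2	1
Snail	p53	-1
Slug	E-cadherin	-1
Tgfb	TgfbR	1
TgfbR	Smad	1
Smad4	Smad	1
Smad	Smad/Miz-1	1
Smad	Myc	-1
Smad	Snail	1
Miz-1	Smad/Miz-1	1
Smad/Miz-1	p21	1
Smad/Miz-1	p15	1
p15	CyclinD	-1
Myc	Myc/Max	1
Max	Myc/Max	1
Myc/Max	Miz-1	-1
Myc/Max	CyclinD	1
Myc/Max	CyclinE	1
Myc/Max	E2f	1
Myc/Max	hTert	1
Myc/Max	p21	-1
Myc/Max	Glut1	1
Myc/Max	Ldha	1
Tnfr	Tradd	1
Tradd	Fadd	1
Tradd	Rip1	1
Tradd	Jnk	1
Rip1	Ikk	1
Jnk	p53	1
Fadd	Casp8	1
Casp8	Caspases	1
Casp8	Bax	1
Ikk	Nf-kB	2
Nf-kB	Bcl-2	2
Nf-kB	Bcl-Xl	1
Nf-kB	Snail	1
Nf-kB	hTert	1
Nf-kB	Vegf	1
Bad	CytC	1
Bad	Bcl-Xl	-1
Puma	CytC	1
Noxa	CytC	1
Bax	CytC	1
Bcl-2	CytC	-1
Bcl-2	Bax	-1
Bcl-2	Bad	-1
Bcl-Xl	CytC	-1
CytC	Apaf	1
CytC	Casp9	1
Apaf	Casp9	1
Casp9	Caspases	1
p53	p53	1
p53	Mdm2	1
p53	p21	1
p53	Puma	1
p53	Noxa	1
p53	Bax	1
p53	Bcl-Xl	-1
p53	p53/Mdm2	1
p53	p53/Pten	1
Mdm2	p53	-1
Mdm2	p53/Mdm2	1
p14ARF	Mdm2	-1
p53/Pten	Pip3	-1
Pten	p53/Pten	1
Shh	Gli	1
Gsk-3	Gli	-1
Gli	CyclinD	1
Gli	Myc	1
CyclinD	Rb	-1
CyclinD	p27	-1
CyclinE	Rb	-1
CyclinE	p27	-1
CyclinE	p21	-1
CyclinE	E2f/CyclinE	1
CyclinA	Rb	-1
CyclinA	E2f	-1
CyclinA	p21	-1
CyclinA	CyclinA	1
CyclinA	Cdh1	-1
CyclinA	UbcH10	1
CyclinB	Rb	-1
CyclinB	E2f	-1
CyclinB	Cdc20	1
CyclinB	Cdh1	-1
CyclinB	UbcH10	1
Rb	E2f	-2
E2f	CyclinE	1
E2f	E2f/CyclinE	1
E2f	p14ARF	1
E2f/CyclinE	CyclinA	1
p21	Rb	1
p21	CyclinE	-1
p27	Rb	1
p27	CyclinE	-1
Cdc20	CyclinB	-1
Cdc20	CyclinA	-1
Cdc20	UbcH10	1
Cdh1	CyclinB	-1
Cdh1	UbcH10	-1
Cdh1	Cdh1/UbcH10	1
UbcH10	Cdh1/UbcH10	1
Cdh1/UbcH10	CyclinA	-1
Rb	CyclinA	-1
p21	CyclinA	-1
p27	CyclinA	-1
p21	CyclinB	-1
CyclinB	p27	-1
CyclinB	p21	-1
Rb	CyclinE	-1
Smad	CyclinE	-1
Akt	mTor	1
Erk	eIf4e	1
Jnk	Bax	1
Pip3	Pkc	1
Ampk	eEf2k	1
p27	CyclinB	-1
Smad	p27	1
Smad	p21	1
Smad	p15	1
Gli	Bcl-2	1
Erk	Vegf	1
Bcl-Xl	Bax	-1
Mdm2	Rb	-1
Cdh1	Cdc20	-1
Cdh1/UbcH10	Cdc20	-1
p53	Tsc1/2	1
Akt	Glut1	1
Akt	Ldha	1
Nutrients	Ampk	-1
GFs	Pi3k	1
Caspases	Rb	-1
Smad	CyclinD	-1
Smad/Miz-1	CyclinD	-1
beta-catenin	CyclinD	1
Ras	CyclinD	1
Akt	Bcl-2	1
Mdm2	p21	-1
Puma	Bax	1
Rip1	Jnk	1
Myc/Max	p27	-1
Myc/Max	p15	-1
Miz-1	p15	1
Erk	Ldha	1
Erk	Glut1	1
mTor	Ldha	1
mTor	Glut1	1
Myc/Max	Vegf	1
Pdk1	Pkc	1
Ampk	p27	1
p53	Vegf	-1
p53	hTert	-1
Myc	Bax	1
Myc	Bcl-2	-1
Gli	Vegf	1
Snail	Bax	-1
Snail	Puma	-1
Akt	Vegf	1
Erk	Mdm2	1
p53	CyclinB	-1
Myc	p14ARF	1
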