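name	threshold	is_input
Carcinogens	0	TRUE
GFs	0	TRUE
Nutrients	0	TRUE
TNFalpha	0	TRUE
Hypoxia	0	TRUE
DNA_damage	0	FALSE
Atm/Atr	0	FALSE
Chk1/2	0	FALSE
Egfr	0	FALSE
Grb2/Sos	0	FALSE
Ras	-1	FALSE
Nf1	-1	FALSE
Raf	0	FALSE
Mek	0	FALSE
Erk	0	FALSE
Plcg	0	FALSE
Pkc	0	FALSE
Pi3k	0	FALSE
Pip3	-1	FALSE
Pten	-1	FALSE
Pdk1	0	FALSE
Akt	1	FALSE
Foxo	-2	FALSE
Tsc1/2	-1	FALSE
Rheb	-1	FALSE
mTor	1	FALSE
eEf2k	-1	FALSE
eEf2	-1	FALSE
eIf4e	0	FALSE
AMP/ATP	-1	FALSE
Ampk	0	FALSE
Phd	-1	FALSE
Vhl	-1	FALSE
Hif1	-2	FALSE
Glut1	1	FALSE
Ldha	1	FALSE
Vegf	0	FALSE
Wnt	0	FALSE
Dsh	0	FALSE
Gsk-3	-3	FALSE
Apc	-1	FALSE
Gsk-3/Apc	1	FALSE
beta-catenin	-1	FALSE
Tcf	0	FALSE
Snail	1	FALSE
Slug	0	FALSE
E-cadherin	-3	FALSE
Tgfb	0	FALSE
TgfbR	0	FALSE
Smad4	-1	FALSE
Smad	1	FALSE
Miz-1	-1	FALSE
Smad/Miz-1	1	FALSE
p15	0	FALSE
Myc	1	FALSE
Max	-2	FALSE
Myc/Max	1	FALSE
hTert	4	FALSE
Tnfr	0	FALSE
Tradd	0	FALSE
Rip1	0	FALSE
Jnk	0	FALSE
Fadd	0	FALSE
Casp8	0	FALSE
Ikk	0	FALSE
Nf-kB	1	FALSE
Bad	-1	FALSE
Puma	0	FALSE
Noxa	0	FALSE
Bax	0	FALSE
Bcl-2	1	FALSE
Bcl-Xl	-1	FALSE
CytC	2	FALSE
Apaf	0	FALSE
Casp9	0	FALSE
Caspases	0	FALSE
p53	0	FALSE
Mdm2	0	FALSE
p53/Mdm2	1	FALSE
p14ARF	3	FALSE
p53/Pten	1	FALSE
Shh	0	FALSE
Gli	0	FALSE
CyclinD	0	FALSE
CyclinE	1	FALSE
CyclinA	0	FALSE
CyclinB	-1	FALSE
Rb	-1	FALSE
E2f	-2	FALSE
E2f/CyclinE	1	FALSE
p21	-2	FALSE
p27	-1	FALSE
Cdc20	0	FALSE
Cdh1	-1	FALSE
UbcH10	-1	FALSE
Cdh1/UbcH10	1	FALSE
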