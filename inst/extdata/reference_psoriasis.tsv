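formulary	medication	column	printed	erratum
CVS	Humira	affected	445-890
CVS	Humira	discontinue	27-80
CVS	Humira	adverse_events	67-311
CVS	Enbrel	affected	151-301
CVS	Enbrel	discontinue	9-27
CVS	Enbrel	adverse_events	23-105
CVS	Cimzia	affected	29-57
CVS	Cimzia	discontinue	2-5
CVS	Cimzia	adverse_events	4-20
CVS	Simponi	affected	16-32
CVS	Simponi	discontinue	1-3
CVS	Simponi	adverse_events	2-11
CVS	Remicade	affected	6-12
CVS	Remicade	discontinue	0.4-1
CVS	Remicade	adverse_events	0.9-4
CVS	Inflectra	affected	3-7
CVS	Inflectra	discontinue	0.2-0.6
CVS	Inflectra	adverse_events	0.2-2	printed low 0.2 inconsistent with the stated 15% of ~3.4 (~0.5)
CVS	Renflexis	affected	0.3-0.7
CVS	Renflexis	discontinue	0.02-0.06
CVS	Renflexis	adverse_events	0.05-0.2
CVS	Avsola	affected	0.2-0.5
CVS	Avsola	discontinue	0.01-0.04
CVS	Avsola	adverse_events	0.03-0.1
CVS	Infliximab	affected	0.2-0.5
CVS	Infliximab	discontinue	0.01-0.04
CVS	Infliximab	adverse_events	0.03-0.1
CVS	Otezla	affected	98-195
CVS	Otezla	discontinue	9-19	printed high 19 inconsistent with the stated 19% of ~196 (~37)
CVS	Otezla	adverse_events	15-68
CVS	Cosentyx	affected	83-167
CVS	Cosentyx	discontinue	8-32
CVS	Cosentyx	adverse_events	13-58
CVS	Stelara	affected	73-146
CVS	Stelara	discontinue	7-28
CVS	Stelara	adverse_events	11-51
CVS	Taltz	affected	71-141
CVS	Taltz	discontinue	6-27
CVS	Taltz	adverse_events	11-49
CVS	Xeljanz	affected	60-120
CVS	Xeljanz	discontinue	5-23
CVS	Xeljanz	adverse_events	9-42
CVS	Tremfya	affected	40-79
CVS	Tremfya	discontinue	4-15
CVS	Tremfya	adverse_events	6-28
CVS	Rinvoq	affected	37-74
CVS	Rinvoq	discontinue	3-14
CVS	Rinvoq	adverse_events	6-26
CVS	Skyrizi	affected	30-60
CVS	Skyrizi	discontinue	3-11
CVS	Skyrizi	adverse_events	5-21
CVS	Siliq	affected	0.8-1.6
CVS	Siliq	discontinue	0.07-0.3
CVS	Siliq	adverse_events	0.1-0.6
CVS	Ilumya	affected	0.7-1.4
CVS	Ilumya	discontinue	0.06-0.3
CVS	Ilumya	adverse_events	0.1-0.5
ESI	Humira	affected	323-647
ESI	Humira	discontinue	19-58
ESI	Humira	adverse_events	113-226	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Enbrel	affected	110-219
ESI	Enbrel	discontinue	6.6-20
ESI	Enbrel	adverse_events	38-77	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Cimzia	affected	21-42
ESI	Cimzia	discontinue	1.2-3.7
ESI	Cimzia	adverse_events	7.3-15	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Simponi	affected	12-23
ESI	Simponi	discontinue	0.7-2.1
ESI	Simponi	adverse_events	4.1-8.2	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Remicade	affected	4.3-8.6
ESI	Remicade	discontinue	0.3-0.8
ESI	Remicade	adverse_events	1.5-3.0	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Inflectra	affected	2.5-5.0
ESI	Inflectra	discontinue	0.2-.04	printed ".04"; the stated 9% of ~5.0 is ~0.4, likely a typo
ESI	Inflectra	adverse_events	0.9-1.7	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Renflexis	affected	0.2-0.5
ESI	Renflexis	discontinue	0.02-0.05
ESI	Renflexis	adverse_events	0.09-0.2	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Avsola	affected	0.2-0.3
ESI	Avsola	discontinue	0.01-0.03
ESI	Avsola	adverse_events	0.06-0.1	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Infliximab	affected	0.2-0.3
ESI	Infliximab	discontinue	0.01-0.03
ESI	Infliximab	adverse_events	0.06-0.1	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Otezla	affected	71-142
ESI	Otezla	discontinue	6.4-27
ESI	Otezla	adverse_events	25-50	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Cosentyx	affected	61-121
ESI	Cosentyx	discontinue	5.5-23
ESI	Cosentyx	adverse_events	21-42	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Stelara	affected	53-106
ESI	Stelara	discontinue	4.8-20
ESI	Stelara	adverse_events	19-37	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Taltz	affected	51-103
ESI	Taltz	discontinue	4.6-19
ESI	Taltz	adverse_events	18-36	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Xeljanz	affected	44-87
ESI	Xeljanz	discontinue	3.9-17
ESI	Xeljanz	adverse_events	15-30	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Tremfya	affected	29-58
ESI	Tremfya	discontinue	2.6-11
ESI	Tremfya	adverse_events	10-20	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Rinvoq	affected	27-54
ESI	Rinvoq	discontinue	2.4-10
ESI	Rinvoq	adverse_events	9.4-19	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Skyrizi	affected	22-44
ESI	Skyrizi	discontinue	2.0-8.3
ESI	Skyrizi	adverse_events	7.7-15	column printed with the 35% rate at both bounds rather than 15-35%
ESI	Siliq	affected	0.6-1.2
ESI	Siliq	discontinue	0.05-0.2
ESI	Siliq	adverse_events	0.2-0.4	column printed with the 35% rate at both bounds rather than 15-35%
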