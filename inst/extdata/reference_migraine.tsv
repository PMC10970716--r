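formulary	medication	column	printed	erratum
CVS	Emgality	affected	858-1050
CVS	Emgality	discontinue	77-200
CVS	Emgality	adverse_events	429-525
CVS	Aimovig	affected	745-911
CVS	Aimovig	discontinue	67-173
CVS	Aimovig	adverse_events	373-455
CVS	Ajovy	affected	413-506
CVS	Ajovy	discontinue	37-96
CVS	Ajovy	adverse_events	207-253
CVS	Vyepti	affected	0.8-1
CVS	Vyepti	discontinue	0.07-0.2
CVS	Vyepti	adverse_events	0.4-0.5
CVS	Nurtec	affected	1,612-1,971
CVS	Nurtec	discontinue	145-374
CVS	Nurtec	adverse_events	806-986
CVS	Qulipta	affected	406-496
CVS	Qulipta	discontinue	37-94
CVS	Qulipta	adverse_events	203-248
ESI	Emgality	affected	625-764
ESI	Emgality	discontinue	56-145
ESI	Emgality	adverse_events	312-382
ESI	Aimovig	affected	542-662
ESI	Aimovig	discontinue	49-103	printed high 103 inconsistent with the stated 19% of 662 (~126)
ESI	Aimovig	adverse_events	271-331
ESI	Ajovy	affected	301-368
ESI	Ajovy	discontinue	27-70
ESI	Ajovy	adverse_events	150-184
ESI	Vyepti	affected	0.6-0.7
ESI	Vyepti	discontinue	0.05-0.14
ESI	Vyepti	adverse_events	0.3-0.4
ESI	Nurtec	affected	1172-1433
ESI	Nurtec	discontinue	106-272
ESI	Nurtec	adverse_events	586-717
ESI	Qulipta	affected	295-361
ESI	Qulipta	discontinue	27-69
ESI	Qulipta	adverse_events	148-180
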