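formulary	medication	column	printed	erratum
CVS	Eliquis	affected	734–1784
CVS	Eliquis	discontinue	125-535
CVS	Eliquis	adverse_events	68-580
CVS	Xarelto	affected	317-771
CVS	Xarelto	discontinue	54-231
CVS	Xarelto	adverse_events	30-251
CVS	Pradaxa	affected	14-34
CVS	Pradaxa	discontinue	2.3-10
CVS	Pradaxa	adverse_events	1.3-11
CVS	Savaysa	affected	0.6-1.5
CVS	Savaysa	discontinue	0.1-0.5
CVS	Savaysa	adverse_events	0.06-0.5
ESI	Eliquis	affected	534-1298
ESI	Eliquis	discontinue	91-389
ESI	Eliquis	adverse_events	50-422
ESI	Xarelto	affected	231-561
ESI	Xarelto	discontinue	39-168
ESI	Xarelto	adverse_events	21-182
ESI	Pradaxa	affected	10-25
ESI	Pradaxa	discontinue	1.7-7.4
ESI	Pradaxa	adverse_events	0.9-8.0
ESI	Savaysa	affected	0.4-1.1
ESI	Savaysa	discontinue	0.08-0.3
ESI	Savaysa	adverse_events	0.04-0.4
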