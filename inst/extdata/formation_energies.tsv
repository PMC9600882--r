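id	name	formula	charge	dfg_prime	dfg_uncertainty
glucose	D-glucose	C6H12O6	0	-917.22	1.3
lactate	L-lactate	C3H5O3	-1	-517.81	0.9
pyruvate	pyruvate	C3H3O3	-1	-474.63	0.8
acetate	acetate	C2H3O2	-1	-369.41	0.5
butyrate	butyrate	C4H7O2	-1	-352.63	1.5
caproate	caproate (hexanoate)	C6H11O2	-1	-335.96	2.9
H+	hydrogen ion (pH 7 activity)	H1	1	-39.96	0
H2O	water	H2O1	0	-237.18	0.2
CO2	carbon dioxide (aqueous)	C1O2	0	-386.02	0.7
H2	dihydrogen (aqueous)	H2	0	17.60	1.0
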