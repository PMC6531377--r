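region	entry
extracellular	I64-L78
extracellular	L137-V178
extracellular	C254-Y271
intracellular	A30-Y43
intracellular	I104-A121
intracellular	L208-H230
binding_site	I60
binding_site	A81-V86
binding_site	Q89
binding_site	K153
binding_site	S156
binding_site	C159
binding_site	G162
binding_site	C166
binding_site	D170
binding_site	V171
binding_site	V239
binding_site	F242
binding_site	A243
binding_site	W246
binding_site	S263
binding_site	L267-Y271
gprotein_interface	R102
gprotein_interface	A105-G114
gprotein_interface	I200
gprotein_interface	A203
gprotein_interface	A204
gprotein_interface	Q207-M211
gprotein_interface	A231
gprotein_interface	S234
gprotein_interface	L235
ec_region	S6-I10
ec_region	T68-F83
ec_region	N145-Y176
ec_region	T256-L272
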