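region	resid
extracellular	64
extracellular	65
extracellular	66
extracellular	67
extracellular	68
extracellular	69
extracellular	70
extracellular	71
extracellular	72
extracellular	73
extracellular	74
extracellular	75
extracellular	76
extracellular	77
extracellular	78
extracellular	137
extracellular	138
extracellular	139
extracellular	140
extracellular	141
extracellular	142
extracellular	143
extracellular	144
extracellular	145
extracellular	146
extracellular	147
extracellular	148
extracellular	149
extracellular	150
extracellular	151
extracellular	152
extracellular	153
extracellular	154
extracellular	155
extracellular	156
extracellular	157
extracellular	158
extracellular	159
extracellular	160
extracellular	161
extracellular	162
extracellular	163
extracellular	164
extracellular	165
extracellular	166
extracellular	167
extracellular	168
extracellular	169
extracellular	170
extracellular	171
extracellular	172
extracellular	173
extracellular	174
extracellular	175
extracellular	176
extracellular	177
extracellular	178
extracellular	254
extracellular	255
extracellular	256
extracellular	257
extracellular	258
extracellular	259
extracellular	260
extracellular	261
extracellular	262
extracellular	263
extracellular	264
extracellular	265
extracellular	266
extracellular	267
extracellular	268
extracellular	269
extracellular	270
extracellular	271
intracellular	30
intracellular	31
intracellular	32
intracellular	33
intracellular	34
intracellular	35
intracellular	36
intracellular	37
intracellular	38
intracellular	39
intracellular	40
intracellular	41
intracellular	42
intracellular	43
intracellular	104
intracellular	105
intracellular	106
intracellular	107
intracellular	108
intracellular	109
intracellular	110
intracellular	111
intracellular	112
intracellular	113
intracellular	114
intracellular	115
intracellular	116
intracellular	117
intracellular	118
intracellular	119
intracellular	120
intracellular	121
intracellular	208
intracellular	209
intracellular	210
intracellular	211
intracellular	212
intracellular	213
intracellular	214
intracellular	215
intracellular	216
intracellular	217
intracellular	218
intracellular	219
intracellular	220
intracellular	221
intracellular	222
intracellular	223
intracellular	224
intracellular	225
intracellular	226
intracellular	227
intracellular	228
intracellular	229
intracellular	230
binding_site	60
binding_site	81
binding_site	82
binding_site	83
binding_site	84
binding_site	85
binding_site	86
binding_site	89
binding_site	153
binding_site	156
binding_site	159
binding_site	162
binding_site	166
binding_site	170
binding_site	171
binding_site	239
binding_site	242
binding_site	243
binding_site	246
binding_site	263
binding_site	267
binding_site	268
binding_site	269
binding_site	270
binding_site	271
gprotein_interface	102
gprotein_interface	105
gprotein_interface	106
gprotein_interface	107
gprotein_interface	108
gprotein_interface	109
gprotein_interface	110
gprotein_interface	111
gprotein_interface	112
gprotein_interface	113
gprotein_interface	114
gprotein_interface	200
gprotein_interface	203
gprotein_interface	204
gprotein_interface	207
gprotein_interface	208
gprotein_interface	209
gprotein_interface	210
gprotein_interface	211
gprotein_interface	231
gprotein_interface	234
gprotein_interface	235
ec_region	6
ec_region	7
ec_region	8
ec_region	9
ec_region	10
ec_region	68
ec_region	69
ec_region	70
ec_region	71
ec_region	72
ec_region	73
ec_region	74
ec_region	75
ec_region	76
ec_region	77
ec_region	78
ec_region	79
ec_region	80
ec_region	81
ec_region	82
ec_region	83
ec_region	145
ec_region	146
ec_region	147
ec_region	148
ec_region	149
ec_region	150
ec_region	151
ec_region	152
ec_region	153
ec_region	154
ec_region	155
ec_region	156
ec_region	157
ec_region	158
ec_region	159
ec_region	160
ec_region	161
ec_region	162
ec_region	163
ec_region	164
ec_region	165
ec_region	166
ec_region	167
ec_region	168
ec_region	169
ec_region	170
ec_region	171
ec_region	172
ec_region	173
ec_region	174
ec_region	175
ec_region	176
ec_region	256
ec_region	257
ec_region	258
ec_region	259
ec_region	260
ec_region	261
ec_region	262
ec_region	263
ec_region	264
ec_region	265
ec_region	266
ec_region	267
ec_region	268
ec_region	269
ec_region	270
ec_region	271
ec_region	272
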