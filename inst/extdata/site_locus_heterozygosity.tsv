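locus	site	Ho	uHe	FIS
PIU76	ME01	0.22	0.93	0.76
PIU76	ME02	0.28	0.94	0.70
PIU76	MO01	0.51	0.90	0.43
PIU76	MO02	0.55	0.92	0.41
PIU76	CH01	0.69	0.90	0.24
PIU76	CH02	0.64	0.91	0.30
PIU66	ME01	0.63	0.76	0.18
PIU66	ME02	0.69	0.79	0.12
PIU66	MO01	0.51	0.81	0.38
PIU66	MO02	0.58	0.79	0.26
PIU66	CH01	0.51	0.73	0.30
PIU66	CH02	0.54	0.73	0.26
PIU20	ME01	0.82	0.93	0.12
PIU20	ME02	0.76	0.93	0.19
PIU20	MO01	0.76	0.91	0.17
PIU20	MO02	0.76	0.92	0.18
PIU20	CH01	0.81	0.91	0.11
PIU20	CH02	0.81	0.91	0.12
PIU67	ME01	0.79	0.90	0.12
PIU67	ME02	0.83	0.88	0.06
PIU67	MO01	0.78	0.84	0.07
PIU67	MO02	0.80	0.87	0.07
PIU67	CH01	0.82	0.83	0.02
PIU67	CH02	0.73	0.82	0.11
PIU19	ME01	0.82	0.94	0.14
PIU19	ME02	0.81	0.95	0.15
PIU19	MO01	0.78	0.92	0.15
PIU19	MO02	0.69	0.92	0.25
PIU19	CH01	0.76	0.91	0.17
PIU19	CH02	0.75	0.90	0.17
PIU90	ME01	0.84	0.90	0.07
PIU90	ME02	0.77	0.89	0.14
PIU90	MO01	0.81	0.85	0.05
PIU90	MO02	0.84	0.86	0.02
PIU90	CH01	0.79	0.85	0.07
PIU90	CH02	0.85	0.85	0.00
PIU36	ME01	0.46	0.92	0.50
PIU36	ME02	0.51	0.92	0.45
PIU36	MO01	0.58	0.90	0.36
PIU36	MO02	0.55	0.88	0.38
PIU36	CH01	0.62	0.88	0.30
PIU36	CH02	0.61	0.89	0.32
PIU82	ME01	0.50	0.86	0.42
PIU82	ME02	0.42	0.84	0.50
PIU82	MO01	0.33	0.88	0.62
PIU82	MO02	0.47	0.90	0.48
PIU82	CH01	0.35	0.89	0.60
PIU82	CH02	0.40	0.88	0.55
PIU17	ME01	0.31	0.95	0.67
PIU17	ME02	0.25	0.94	0.74
PIU17	MO01	0.38	0.95	0.60
PIU17	MO02	0.40	0.94	0.57
PIU17	CH01	0.44	0.94	0.53
PIU17	CH02	0.42	0.95	0.56
PIU06	ME01	0.51	0.84	0.40
PIU06	ME02	0.47	0.88	0.47
PIU06	MO01	0.81	0.52	-0.57
PIU06	MO02	0.77	0.59	-0.30
PIU06	CH01	0.77	0.53	-0.46
PIU06	CH02	0.87	0.55	-0.60
multilocus	ME01	0.59	0.89	0.34
multilocus	ME02	0.58	0.90	0.35
multilocus	MO01	0.63	0.85	0.23
multilocus	MO02	0.64	0.86	0.23
multilocus	CH01	0.66	0.84	0.19
multilocus	CH02	0.66	0.84	0.18
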