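system	pathway	n_nodes	spl	spl_sd
M2/2CU	2CU-A191-W155-A194-V111-L115-F119-C124-K221-E223-Nb9	9	6.60	1.00
M2/IXO	IXO-S151-W400-N436-Y440-R121-Nb9	5	4.40	1.10
F396A	2CU-W422-G425-L428-I431-T434-T37-G40-L43-F451-Nb9	9	5.63	1.10
F396A	IXO-W400-Y196-V199-T203-W207-A212-R216-K218-E220-Nb9	9	7.58	1.20
Y403A	2CU-Y104-A109-W148-I144-S64-Y60-N58-N444-Nb9	8	5.89	1.10
Y403A	IXO-N108-N113-S64-Y60-N58-N444-Nb9	6	7.96	1.20
Bound M2	2CU-I178-Y403-W400-F396-L114-Y440-Nb9	6	4.20	0.90
Bound M2	IXO-V111-F396-L114-Y440-Nb9	4	3.60	0.80
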