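CAS	Cramer class	Local_NOEC_ppm	Systemic_NOEC_ppm	General_NOEC_ppm
00001-01-1	I	50	20	20
00002-02-2	I	NA	35	35
00003-03-3	I	80	100	80
00004-04-4	III	5	2	
00005-05-5	III	NA	0.7	0.7
00006-06-6	III	12	9	9
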