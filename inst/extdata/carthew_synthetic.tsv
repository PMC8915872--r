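Name	Cramer class	Local NOAEC (mg/m^3)	Systemic NOAEL (mg/kg/day)
synthetic-aerosol-1	I	120	25
synthetic-aerosol-2	I	45	8
synthetic-aerosol-3	I	300	60
synthetic-aerosol-4	I	12	2.5
synthetic-aerosol-5	III	5	1.2
synthetic-aerosol-6	III	0.8	0.3
synthetic-aerosol-7	III	15	4
synthetic-aerosol-8	III	2.4	0
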