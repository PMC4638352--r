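gene_id	coef	hr_printed	p_value
ZNF536	51.36	2.03e22	0.000563
NARS	53.32	1.44e23	0.004414
ZNF592	30.54	1.83e13	0.00128
SLC25A21	51.58	2.52e22	0.008259
HERPUD2	27.91	1.32e12	0.009686
PFN1	-53.98	3.60e-24	0.002025
ZFAND5	-45.85	1.23e-20	0.002271
NRIP2	-40.55	2.45e-18	0.000455
HPX	-29.21	2.06e-13	0.002975
DPAGT1	-34.23	1.36e-15	0.001741
TMEM184B	-42.54	3.35e-19	0.008188
PPP1R12C	-41.23	1.24e-18	0.000633
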