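table	traits	lod	p_printed
3	MRI-PDFF	2.9010	1.29e-4
3	HOMA-IR	2.4948	3.50e-4
3	HOMA-IR	2.1086	9.16e-4
3	VAT	2.415	4.27e-4
3	VAT	2.2385	6.62e-4
3	VAT	2.2037	7.22e-4
3	HDL-C	3.0872	8.14e-5
3	HDL-C	2.4495	3.92e-4
4	MRI-PDFF+HOMA-IR	2.1144	9.03e-4
4	MRI-PDFF	1.7703	2.15e-3
4	HOMA-IR	1.6081	3.25e-3
4	MRI-PDFF+HOMA-IR	2.0901	9.60e-4
4	HOMA-IR	0.1527	0.201
4	MRI-PDFF+VAT	2.3459	5.07e-4
4	MRI-PDFF	0.1298	0.220
4	VAT	1.3833	5.80e-3
4	MRI-PDFF+HDL-C	2.3635	4.85e-4
4	MRI-PDFF	0.0535	0.310
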