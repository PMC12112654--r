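endophenotype	class	n	erv_printed	p	rho_g	se_rho_g	h2_e	se_h2_e
HOMA-IR	glucose homeostasis	662	0.406	1.727e-8	0.847	0.078	0.443	0.090
FI	glucose homeostasis	688	0.364	9.568e-8	0.822	0.082	0.377	0.086
FG	glucose homeostasis	670	0.282	1.780e-5	0.599	0.109	0.424	0.081
VAT	adiposity distribution	704	0.392	6.960e-8	0.666	0.078	0.665	0.080
WC	adiposity distribution	704	0.269	1.099e-3	0.518	0.085	0.520	0.079
BMI	adiposity distribution	704	0.267	9.350e-5	0.496	0.098	0.558	0.076
DXA %BF	adiposity distribution	676	0.263	2.054e-4	0.521	0.107	0.493	0.090
SAT	adiposity distribution	704	0.261	1.700e-4	0.518	0.104	0.487	0.081
HDL-C	CVD risk factors	693	0.332	3.480e-5	-0.593	0.121	0.603	0.080
TG	CVD risk factors	693	0.293	4.780e-5	0.564	0.100	0.519	0.086
MAP	CVD risk factors	704	0.187	7.750e-3	0.424	0.142	0.373	0.087
SBP	CVD risk factors	704	0.172	1.148e-2	0.393	0.140	0.367	0.084
DBP	CVD risk factors	704	0.169	1.860e-2	0.406	0.158	0.334	0.093
ALT	liver function	623	0.163	0.029	0.449	0.185	0.253	0.098
AST	liver function	623	0.047	0.508	0.126	0.187	0.274	0.089
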