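pair	function_id	description	var_ind	var_int	extra_var	p_ind	fdr
Alistipes-Sporobacter	EC:1.14.14.1	Unspecific monooxygenase	0.02762911	0.02874302	0.00111391	0.00022366	0.00067097
Anaerotignum-Barnesiella	EC:2.5.1.46	Deoxyhypusine synthase	0.03834184	0.0462416	0.00789976	8.0578e-6	2.4173e-5
Anaerotignum-Barnesiella	EC:1.14.14.1	Unspecific monooxygenase	0.01542343	0.03128079	0.01585737	0.00943734	0.01415601
Anaerotignum-Neglecta	EC:2.5.1.46	Deoxyhypusine synthase	0.0390983	0.04792689	0.00882859	6.3634e-6	1.909e-5
Anaerotignum-Neglecta	EC:1.14.14.1	Unspecific monooxygenase	0.01465138	0.01794392	0.00329254	0.01193917	0.01790876
Anaerotignum-Barnesiella	KO:K00809	deoxyhypusine synthase	0.03850055	0.04644554	0.00794499	7.6685e-6	7.6685e-6
Anaerotignum-Neglecta	KO:K00809	deoxyhypusine synthase	0.03925636	0.04811791	0.00886155	6.057e-6	6.057e-6
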