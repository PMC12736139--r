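pair	TE_nonMetS	TE_MetS	seTE_nonMetS	seTE_MetS	hetero_p	I2
Alistipes-Sporobacter	-0.1516305	-0.4312161	0.06792643	0.11578319	0.03727255	0.76947448
Anaerotignum-Barnesiella	0.23093215	0.02179268	0.05177804	0.06868028	0.01503502	0.83086279
Anaerotignum-Neglecta	0.32789629	0.03903557	0.08833262	0.06868028	0.00983372	0.84995738
Bacteroides-Pseudoclostridium	-0.2899035	-0.0958833	0.05177804	0.06868028	0.02408619	0.80347517
Enterococcus-Tyzzerella	0.30805484	0.05858727	0.05177804	0.06868028	0.00372682	0.88112707
Eubacterium-Terrisporobacter	-0.1575766	0.06119389	0.05177804	0.06868028	0.01097453	0.84542702
Muribaculum-Weissella	0.20824215	0.02352035	0.05177804	0.06868028	0.03174194	0.78319221
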