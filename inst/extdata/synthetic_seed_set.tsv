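id	family	catalytic_class	catalytic_positions
FAM01_seed	FAM01	serine	12,21,22
FAM02_seed	FAM02	cysteine	60,83
FAM03_seed	FAM03	aspartyl	19,81
FAM04_seed	FAM04	metallo	37,57,97
FAM05_seed	FAM05	serine	48,76,78
FAM06_seed	FAM06	cysteine	62,92
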