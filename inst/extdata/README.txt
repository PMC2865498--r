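Synthetic demonstration seed set (6 random protease-like proteins with
assigned families, catalytic classes and catalytic positions), generated
by demo_seed_set(6, protein_length = c(120, 160), rng_seed = 42).
Carries no biological information; used in examples and format tests.
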