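id	formula	dg0_prime_kj_mol
R1	C0 <=> C1	-4
R2	C1 <=> C2	-4
R3	C2 <=> C3	-4
R4	C3 <=> C4	-4
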