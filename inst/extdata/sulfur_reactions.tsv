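name	equation	dg0_prime_kj
acetate_elemental_sulfur_reduction	Acetate- + 4S0 + 4H2O -> 4HS- + 2HCO3- + 5H+	-6.6
acetate_tetrathionate_reduction	Acetate- + 4S4O62- + 4H2O -> 2HCO3- + 9H+ + 8S2O32-	-233.4
acetate_sulfate_reduction	Acetate- + SO42- -> 2HCO3- + HS-	-47.3
hydrogenotrophic_sulfate_reduction	4H2 + SO42- + H+ -> HS- + 4H2O	-151.9
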