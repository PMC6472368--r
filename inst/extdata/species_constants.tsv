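name	formula	charge	phase	dGf0_kJ_mol	dHf0_kJ_mol	provenance
H+	H1	1	aqueous	0	0	convention: 1 M standard state, dGf0 = dHf0 = 0
H2(g)	H2	0	gas	0	0	element reference state
H2(aq)	H2	0	aqueous	17.6	-4.2	dissolved-hydrogen standard tables (Thauer-style compilation)
H2O	H2O1	0	liquid	-237.18	-285.83	standard thermodynamic tables (Madigan-style compilation)
HCO3-	C1H1O3	-1	aqueous	-586.85	-692.0	standard thermodynamic tables (Madigan-style compilation)
acetate	C2H3O2	-1	aqueous	-369.41	-486.01	standard thermodynamic tables (Madigan/Thauer-style compilation)
SO4-2	O4S1	-2	aqueous	-744.6	-909.27	standard thermodynamic tables (Madigan-style compilation)
HS-	H1S1	-1	aqueous	12.1	-17.6	standard thermodynamic tables (Madigan-style compilation)
benzoate	C7H5O2	-1	aqueous	-245.6	-386.318	dGf0: aromatic-compound energetics compilation (Dolfing-style); dHf0: back-derived from the benzoate complete-oxidation standard enthalpy (29.4 kJ) via derive_formation_energy
hexadecane	C16H34	0	aqueous	49.473	-455.853	back-derived from the hexadecane acetogenic-oxidation standard energies (176.3 / 98.4 kJ) via derive_formation_energy
CH4(g)	C1H4	0	gas	-50.75	-74.85	standard thermodynamic tables (Madigan-style compilation)
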