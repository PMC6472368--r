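reaction_id	label	class	equation
R1	Hexadecane hydrogenogenic oxidation	hydrogenogenic_oxidation	hexadecane:-1;H2O:-16;acetate:8;H2(aq):17;H+:8
R2	Hexadecane acetogenic oxidation	acetogenic_oxidation	hexadecane:-1;HCO3-:-8.5;acetate:12.25;H+:3.75;H2O:1
R3	Hexadecane complete oxidation (sulfate-coupled)	complete_oxidation	hexadecane:-1;SO4-2:-12.25;HCO3-:16;HS-:12.25;H2O:1;H+:3.75
R4	Benzoate hydrogenogenic oxidation	hydrogenogenic_oxidation	benzoate:-1;H2O:-7;acetate:3;HCO3-:1;H2(aq):3;H+:3
R5	Benzoate acetogenic oxidation	acetogenic_oxidation	benzoate:-1;HCO3-:-0.5;acetate:3.75;H+:2.25
R6	Benzoate complete oxidation (sulfate-coupled)	complete_oxidation	benzoate:-1;SO4-2:-3.75;H2O:-4;HCO3-:7;HS-:3.75;H+:2.25
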