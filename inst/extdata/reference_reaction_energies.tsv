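reaction_id	dG0_kJ	dH0_kJ
R1	1089.1	1069.8
R2	176.3	98.4
R3	-407.3	24.9
R4	120.9	117.4
R5	-846.3	-1091.3
R6	-76.2	29.4
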