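family_id	pathway	description
K00844	emp	hexokinase
K01810	emp	glucose-6-phosphate isomerase
K00850	emp	6-phosphofructokinase
K01623	emp	fructose-bisphosphate aldolase class I
K01803	emp	triosephosphate isomerase
K00134	emp	glyceraldehyde-3-phosphate dehydrogenase
K00927	emp	phosphoglycerate kinase
K01834	emp	phosphoglycerate mutase
K01689	emp	enolase
K00873	emp	pyruvate kinase
K01897	beta_oxidation	long-chain acyl-CoA synthetase
K06445	beta_oxidation	acyl-CoA dehydrogenase
K01825	beta_oxidation	enoyl-CoA hydratase / 3-hydroxyacyl-CoA dehydrogenase (fadB)
K00632	beta_oxidation	acetyl-CoA acyltransferase (fadA)
K01782	beta_oxidation	multifunctional beta-oxidation protein (fadJ)
K07516	beta_oxidation	3-hydroxyacyl-CoA dehydrogenase (fadN)
K00198	wood_ljungdahl	anaerobic CO dehydrogenase catalytic subunit (cooS/acsA)
K14138	wood_ljungdahl	acetyl-CoA synthase (acsB)
K00197	wood_ljungdahl	CODH/ACS complex gamma subunit (cdhE)
K00194	wood_ljungdahl	CODH/ACS complex delta subunit (cdhD)
K01938	wood_ljungdahl	formate--tetrahydrofolate ligase (fhs)
K01491	wood_ljungdahl	methylenetetrahydrofolate dehydrogenase/cyclohydrolase (folD)
K00297	wood_ljungdahl	methylenetetrahydrofolate reductase (metF)
K15023	wood_ljungdahl	methyltetrahydrofolate corrinoid methyltransferase (acsE)
K01647	tca	citrate synthase
K01681	tca	aconitate hydratase
K00031	tca	isocitrate dehydrogenase
K00164	tca	2-oxoglutarate dehydrogenase E1
K01902	tca	succinyl-CoA synthetase alpha subunit
K01903	tca	succinyl-CoA synthetase beta subunit
K00239	tca	succinate dehydrogenase flavoprotein subunit
K01676	tca	fumarate hydratase class I
K00024	tca	malate dehydrogenase
K00016	lactate_fermentation	L-lactate dehydrogenase
K00001	ethanol_fermentation	alcohol dehydrogenase
K11180	dsrAB	dissimilatory sulfite reductase alpha subunit (dsrA)
K11181	dsrAB	dissimilatory sulfite reductase beta subunit (dsrB)
K21647	rdhA	reductive dehalogenase catalytic subunit
K00399	mcrA	methyl-coenzyme M reductase alpha subunit
assA	fumarate_addition	alkylsuccinate synthase catalytic subunit
bssA	fumarate_addition	benzylsuccinate synthase catalytic subunit
bamB	benzoyl_coa	class I benzoyl-CoA reductase component (bcrB-like)
hyd_FeFe_A	hydrogenase_FeFe	FeFe hydrogenase group A catalytic subunit
hyd_NiFe_1a	hydrogenase_NiFe_1	NiFe hydrogenase group 1a catalytic subunit
hyd_NiFe_3b	hydrogenase_NiFe_3	NiFe hydrogenase group 3b catalytic subunit
hyd_NiFe_3c	hydrogenase_NiFe_3	NiFe hydrogenase group 3c catalytic subunit
hyd_NiFe_4	hydrogenase_NiFe_4	NiFe hydrogenase group 4 catalytic subunit
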