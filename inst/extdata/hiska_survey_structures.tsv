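pdb_id	protein	ph	ph_range	mother_liquor	sulfate_at_his
3DGE	HK853	5.6	NA	1.7 M (NH4)2SO4, 2.5% dioxane, 0.1 M citrate, pH 5.6	FALSE
5UHT	HK853	5.0	NA	0.1 M citric acid (pH 4), 0.8 M NH4SO4; adjusted final pH to 5.0	FALSE
2C2A	HK853	6.5	NA	1.25 M Li2SO4, 0.1 M NH4 acetate pH 6.5	TRUE
4JAU	HK853	8.5	NA	8% PEG 4000, 0.8 M LiCl2, 0.1 M Tris-HCl pH 8.5	FALSE
4JAS	HK853	5.5	NA	2.2 M (NH4)2SO4, 0.1 M Bis-Tris pH 5.5	FALSE
4JAV	HK853	5.5	NA	2.2 M (NH4)2SO4, 0.1 M Bis-Tris pH 5.5	TRUE
4I5S	VicK	8.1	7.6-8.6	2.3-2.9 M Na formate, 3% PEG 4000	FALSE
4U7N	WalK	5.6	NA	1.0 M (NH4)2SO4, 1% PEG 4000, 50 mM Bis-Tris pH 5.6	FALSE
5C93	WalK	5.6	NA	1.0 M (NH4)2SO4, 1% PEG 4000, 50 mM Bis-Tris pH 5.6	TRUE
4U7O	WalK	5.6	NA	1.0 M (NH4)2SO4, 1% PEG 4000, 50 mM Bis-Tris pH 5.6	FALSE
4ZKI	WalK	5.6	NA	1.0 M (NH4)2SO4, 1% PEG 4000, 50 mM Bis-Tris pH 5.6	FALSE
3ZRV	EnvZ-HAMP-DHp	7.0	NA	20% PEG 4000, 20% isopropanol, 0.1 M tri-sodium citrate pH 5.6	FALSE
3ZRX	EnvZ-HAMP-DHp	4.6	NA	30% MPD, 0.02 M CaCl2, 0.1 M sodium acetate	FALSE
3ZRW	EnvZ-HAMP-DHp	7.0	NA	0.4 M Mg formate, 0.1 M Bis-Tris, pH 7	FALSE
5B1N	EnvZ-DHp	6.9	NA	1.1-1.3 M Na/K phosphate	FALSE
5B1O	EnvZ-DHp	6.9	NA	0.1 M magnesium formate, 15% PEG 3350	FALSE
4KP4	EnvZ-chimera	7.5	NA	1.5 M (NH4)2SO4, 2% PEG 1000, 2% PEG 4000, 0.03 M Na acetate, 0.1 M HEPES pH 7.5	FALSE
4BIU	CpxA	8.5	NA	1.75 M (NH4)2SO4, 25% glycerol, 0.1 M Tris-HCl pH 8.5	FALSE
4BIW	CpxA	8.5	NA	1.75 M (NH4)2SO4, 25% glycerol, 0.1 M Tris-HCl pH 8.5	FALSE
5LFK	CpxA	8.5	NA	1.5 M (NH4)2SO4, 12% glycerol, 0.1 M Tris-HCl pH 8.5	FALSE
4BIV	CpxA	8.5	NA	1.75 M (NH4)2SO4, 25% glycerol, 0.1 M Tris-HCl pH 8.5	FALSE
4CB0	CpxA	8.5	NA	1.75 M (NH4)2SO4, 25% glycerol, 0.1 M Tris-HCl pH 8.5	FALSE
4BIX	CpxA	8.5	NA	25% PEG 3350, 0.2 M Li2SO4, 0.1 M Tris-HCl pH 8.5	FALSE
4BIY	CpxA	8.5	NA	25% PEG 3350, 0.2 M Li2SO4, 0.1 M Tris-HCl pH 8.5	FALSE
4CTI	EnvZ-HAMP-Af1503	4.0	NA	20% PEG 3350, 0.2 M lithium acetate, 0.1 M MMT buffer pH 4.0	FALSE
5UKV	PhoR-DHp	7.2	NA	35% PEG 200, 2 mM EDTA, 0.2 M KI, 0.1 M Na/K phosphate pH 7.2	FALSE
4MT8	ERS1-DHp	7.5	NA	9% PEG 3350, 0.18 M L-proline, 0.1 M HEPES pH 7.5	FALSE
6DK7	RetS-DHp-CA	7.5	NA	2.7 M NaCl, 9 mM CoCl2, 90 mM HEPES pH 7.5	FALSE
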