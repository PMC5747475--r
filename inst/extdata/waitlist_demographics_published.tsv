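variable	category	count_pre	count_post
age_group	18-39	16139	2295
age_group	40-64	62804	8289
age_group	>=65	18850	2529
gender	Male	59960	8273
gender	Female	37833	4840
abo	O	47033	6254
abo	A	32804	4410
abo	B	14025	1905
abo	AB	3931	544
race	White	43539	5677
race	Black	28304	3657
race	Hispanic	17649	2564
race	Asian	6275	955
race	Other	2026	260
esrd_diagnosis	Diabetes	35000	4771
esrd_diagnosis	Glomerulonephritis	10971	1436
esrd_diagnosis	Graft Failure	1950	265
esrd_diagnosis	Hypertension	22962	2841
esrd_diagnosis	Other	26910	3800
pra_category	0-79%	95925	12884
pra_category	80-89%	575	56
pra_category	90-94%	356	45
pra_category	95-98%	443	62
pra_category	99-100%	494	66
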