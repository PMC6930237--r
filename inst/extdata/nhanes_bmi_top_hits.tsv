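# Published NHANES 1999-2006 BMI EWAS: the 16 exposures replicating at dual
# Bonferroni-corrected p < 0.05. Raw (unadjusted) p-values as printed for the
# Discovery analysis (family of 332 tests) and Replication analysis (family
# of 99 tests). Input data for multiple-testing reproduction checks.
variable	category	description	pvalue_discovery	pvalue_replication
LBXGTC	nutrients	g-Tocopherol (ug/dL)	2.611e-14	2.729e-11
LBXIRN	nutrients	Iron (ug/dL)	3.283e-11	1.748e-12
URXUPT	heavy metals	Platinum, urine (ug/L)	1.281e-10	2.322e-04
total_days_drink_year	alcohol use	days drink in year	4.563e-07	1.710e-10
LBXBEC	nutrients	trans-Beta carotene (ug/dL)	8.394e-07	1.690e-08
cigarette_smoking	smoking behavior	Current Cigarette Smoker	8.735e-07	8.627e-05
LBXCBC	nutrients	cis-Beta carotene (ug/dL)	9.142e-07	1.159e-09
LBXCOT	cotinine	Cotinine (ng/mL)	3.989e-06	9.673e-07
LBXLUZ	nutrients	Lutein and zeaxanthin (ug/dL)	8.463e-06	2.312e-11
SMQ040	smoking behavior	Do you now smoke cigarettes	1.509e-05	3.521e-05
LISINOPRIL	pharmaceutical	LISINOPRIL	2.919e-05	1.665e-08
LBXBPB	heavy metals	Lead (ug/dL)	3.858e-05	1.106e-07
LBXVID	nutrients	Vitamin D (ng/mL)	4.627e-05	3.048e-12
DR1TALCO	food component recall	Alcohol (gm)	8.099e-05	9.210e-06
LBXBCD	heavy metals	Cadmium (ug/L)	1.087e-04	6.826e-07
DR1TP204	food component recall	PFA 20:4 Eicosatetraenoic (gm)	1.329e-04	1.573e-05
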