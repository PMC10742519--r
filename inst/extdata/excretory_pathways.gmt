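ALDO	hsa04960 Aldosterone-regulated sodium reabsorption (curated subset)	ATP1A1	ATP1B1	ATP1B2	FXYD2	FXYD4	HSD11B2	IGF1	IGF1R	INSR	KCNJ1	KRAS	MAPK1	MAPK3	NEDD4L	NR3C2	PDPK1	PIK3CA	PIK3CB	PIK3CD	PIK3R1	PIK3R2	PRKCA	PRKCB	SCNN1A	SCNN1B	SCNN1G	SFN	SGK1
COLL	hsa04966 Collecting duct acid secretion (curated subset)	ATP6V0A1	ATP6V0A4	ATP6V1A	ATP6V1B1	ATP6V1B2	ATP6V1C1	ATP6V1E1	ATP6V1G3	CA2	CLCNKB	KCNJ1	SLC26A7	SLC4A1	SLC9A1
ENDO	hsa04961 Endocrine and other factor-regulated calcium reabsorption (curated subset)	ADCY6	ADCY9	AP2A1	AP2A2	AP2S1	ATP1A1	ATP1A2	ATP1A3	ATP1A4	ATP1B1	ATP1B2	ATP1B3	ATP2B3	BDKRB2	CLTA	CLTB	CLTCL1	DNM1	DNM2	DNM3	ESR1	FXYD2	GNAQ	GNAS	KL	KLK2	PLCB1	PLCB2	PRKCA	PRKCB	SLC8A1	VDR
PROX	hsa04964 Proximal tubule bicarbonate reclamation (curated subset)	AQP1	ATP1A1	ATP1B1	CA2	CA4	FXYD2	GLS	GLS2	GLUD1	MDH1	PCK1	SLC38A3	SLC4A4	SLC9A3
VASO	hsa04962 Vasopressin-regulated water reabsorption (curated subset)	ADCY6	ADCY9	AQP2	AQP3	AQP4	ARHGDIA	ARHGDIB	AVP	AVPR2	CREB3	CREB3L1	CREB3L2	CREB3L3	CREB3L4	DCTN1	DCTN2	DYNC1H1	DYNC1I1	DYNC1LI1	DYNC2LI1	GNAS	NSF	PRKACA	PRKACB	PRKX	RAB11A	RAB5A	RAB5B	STX4	VAMP2
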