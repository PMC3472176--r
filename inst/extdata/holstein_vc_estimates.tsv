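# Published REML variance-component estimates for six production and fitness
# traits of genotyped Nordic Holstein bulls (deregressed proofs, 44K SNP
# panel).  Columns: model-1 animal-model additive variance and VR; model-2
# genomic variance and VR; model-3 joint genomic (sigma_g3) and residual
# polygenic (sigma_a3) variances and VR; model-4 per-chromosome genomic
# variances summed over the 29 autosomes (sum_chrom).
trait	type	sigma_a1	vr1	sigma_g2	vr2	sigma_g3	sigma_a3	vr3	sum_chrom
milk	production	138.24	0.92	134.18	0.88	119.49	20.87	0.93	115.3
fat	production	113.10	0.91	109.33	0.87	93.61	22.36	0.94	90.5
protein	production	143.16	0.97	132.99	0.88	106.67	34.26	0.96	103.0
fertility	fitness	151.74	0.78	142.42	0.74	110.38	40.10	0.78	106.5
health	fitness	141.57	0.65	136.70	0.63	101.84	42.60	0.66	98.4
mastitis	fitness	99.19	0.82	97.30	0.79	81.77	23.67	0.85	79.0
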