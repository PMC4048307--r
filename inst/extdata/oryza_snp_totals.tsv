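accession	genome_total_snps	genome_snps_per_kb	chr5_total_snps	chr5_snps_per_kb	desert_snp_count	desert_snps_per_kb
indica	978630	2.56	68443	2.28	244	0.053
rufipogon_asian	917738	2.40	70367	2.34	6050	1.302
rufipogon_australian	2564013	6.71	219794	6.71	18179	3.96
meridionalis	2418084	6.33	206884	6.89	17139	3.73
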