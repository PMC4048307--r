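locus	length_kb	count_indica	density_indica	count_rufipogon_asian	density_rufipogon_asian	count_rufipogon_australian	density_rufipogon_australian	count_meridionalis	density_meridionalis
GS3	357	25	0.07	884	2.48	2910	8.15	2650	7.42
Bh4	374	98	0.26	1126	3.01	3313	8.86	2737	7.32
sh4	371	178	0.48	694	1.87	2711	7.29	3247	8.73
qSW5	151	8	0.05	522	3.46	1564	10.36	1451	9.61
wx	369	27	0.07	967	2.62	3209	8.7	3098	8.40
PROG1	267	25	0.09	647	2.42	1634	6.12	1647	6.17
Rc	488	74	0.15	1359	2.78	2922	5.99	2069	4.24
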