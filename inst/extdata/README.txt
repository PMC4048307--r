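Published summary tables from a whole-genome resequencing comparison of one
cultivated rice accession (O. sativa ssp. indica) and three wild AA-genome
relatives (Asian O. rufipogon, Australian O. rufipogon, O. meridionalis),
each mapped to the O. sativa ssp. japonica cv. Nipponbare reference.

oryza_snp_totals.tsv
  Per-accession SNP totals and SNPs/kb as printed: whole genome, chromosome
  5, and the chromosome 5 "polymorphism desert" (8.972-13.557 Mb, 4585 kb).
  Printed densities are kept verbatim; counts and interval lengths are the
  inputs from which the package's density arithmetic is checked.

oryza_sweep_table.tsv
  Per-locus selective-sweep table: length of the low-polymorphism region
  (delineated on the cultivated accession) and each accession's SNP count
  and printed SNPs/kb over that region, for the 7 of 15 candidate
  domestication/improvement loci with a detectable sweep.
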