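---
title: "Methods: windowed SNP density, polymorphism deserts and selective sweeps"
author: "desertscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed SNP density, polymorphism deserts and selective sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desertscan)
```

## The problem

When several rice accessions — cultivated lines and their wild AA-genome
relatives — are resequenced and mapped against one reference genome, the
density of single-nucleotide substitutions along each chromosome is a direct
readout of how much variation each lineage retains. Three patterns carry the
signal this package is built to measure:

* **Polymorphism deserts**: multi-hundred-kilobase regions where the
  cultivated genome carries almost no SNPs relative to the reference (on the
  order of fewer than 10 SNPs per 100 kb against a chromosomal mean of
  ~250). When wild relatives that never passed through domestication also
  show depressed (though not absent) diversity over the same interval, the
  desert plausibly predates domestication — the signature of natural
  selection in the wild progenitor rather than of the domestication
  bottleneck.
* **Selective sweeps** around individual domestication and improvement
  loci: narrower intervals (roughly 150–500 kb) of depressed diversity
  centred on genes that were targets of human selection.
* **Gene-level diversity**: within a region of interest, per-gene SNP
  densities and the split into synonymous and nonsynonymous coding changes,
  after discarding genes without adequate sequencing depth in every
  accession.

All statistics operate on raw SNP density (SNPs per kb). Population-genetic
estimators that model allele frequencies (pi, theta, Tajima's D, Fst) are
deliberately out of scope: the input is one call set per accession against a
reference, with no within-accession frequency information.

## Data model and conventions

Every coordinate inside the package is 1-based and inclusive, matching VCF
and GFF3; BED input/output is converted at the boundary (BED is 0-based,
half-open). A call set holds at most one biallelic substitution per
(chromosome, position) for one accession: multi-allelic VCF records are
decomposed and the first alternate allele kept, so one polymorphic position
counts once; indels and MNPs are excluded throughout. Genotype columns are
ignored — the presence of a record means the accession differs from the
reference there. Each reader accounts for what it drops: kept plus dropped
records always equals the number of input lines.

## Windowed scans and density arithmetic

Chromosomes are tiled with non-overlapping ("tumbling") windows of 100 kb
by default: `[1, 100000]`, `[100001, 200000]`, and so on. The terminal
window keeps its true (shorter) length and is flagged `partial`; it
contributes to totals but is excluded from equal-support statistics such as
the desert t-test. A `step_bp` argument smaller than the window width gives
genuinely sliding windows when wanted, at the cost of the conservation
property (window counts summing to the call-set size), which holds only for
the tumbling case.

Region densities are reported as `count / length_kb`, rounded **half-up**
(2.475 prints as 2.48) to the number of decimals being reported, because
that is how per-region SNPs-per-kb values are conventionally printed;
`round()`'s round-to-even rule would disagree with published tables in
exactly the tie cases. All internal computation is unrounded.

## Desert detection

A window is *low* when its SNP count falls below a threshold rate of 10
SNPs per 100 kb, pro-rated to the window's true length (so a 50-kb scan is
thresholded at 5). A desert is a maximal run of low windows, allowing at
most `max_gap_windows` consecutive non-low windows inside the run, and is
reported when it contains at least `min_windows` low windows.

The defaults (`min_windows = 4`, `max_gap_windows = 1`) were set from the
Poisson arithmetic of the scenario the simulator emulates, before any tests
were run. In a desert at 2% of a 2.5 SNPs/kb background, a 100-kb window
holds Poisson(5) SNPs and exceeds the threshold of 10 with probability
about 0.032. A strict-run rule (`max_gap = 0`) therefore splits a five-window
desert whenever a single interior window fluctuates high — about one run in
seven — and a five-window minimum then discards the fragments entirely.
Bridging one high window and accepting four-window (400 kb) runs brings the
failure probability of recovering a 500-kb desert to roughly half a percent
while still refusing single- and double-window noise. Published desert
delimitation rules rarely state their gap policy; these defaults are an
explicit analysis choice, exposed as parameters, not a reconstruction of
any particular study's rule.

The desert-versus-rest comparison is a two-sided **Welch** (unequal
variance) two-sample t-test on per-window densities, inside the region
against the remainder of the same chromosome. Welch rather than Student
because the two samples differ wildly in both size and variance (a desert's
per-window variance is tiny); with equal inputs the choice is immaterial,
and where the source of the convention says only "t-test", the
unequal-variance form is the safe default. The degenerate case of exactly
constant densities on both sides returns t = 0, p = 1 rather than an error.
Partial terminal windows are excluded from both samples.

`centromere_context()` asks whether a desert is explained by centromeric
recombination suppression alone: it compares the density within a ±1 Mb
interval around the centromere midpoint with the chromosome-wide mean.
Note the ratio's denominator is the whole-chromosome mean *including* the
centromeric interval itself, so a planted suppression of 0.5 over the
interval yields a ratio above 0.5 (the denominator is diluted); the
planted-truth tests account for this.

## Sweep delineation

Around each candidate locus a ±1 Mb interval is extracted and scanned at
1-kb resolution. At that resolution a cultivated-like background of
2.5 SNPs/kb gives per-window counts of mean 2.5 — far too noisy to
threshold directly — so the window densities are smoothed with a centred
rolling mean of `smooth_k = 51` windows (shrinking at the interval edges).
51 kb balances noise suppression against the smallest sweep the method
should resolve (~150 kb). The sweep is the maximal run of consecutive
smoothed windows below `frac_threshold` times the chromosomal mean density
that contains the locus window; if the locus window itself is not below
threshold, no sweep is reported. Length, SNP count and density are then
measured on the raw windows of the run, so `density * length_kb` equals the
count exactly.

`frac_threshold` defaults to **0.5**. The choice is an edge-estimation
argument: the smoothed profile crosses a threshold `t` where a fraction
`(background - t) / (background - floor)` of the smoothing window lies
inside the sweep. With a deep sweep (floor near zero), `t` at half the
background puts the crossing almost exactly at the true edge — the
half-amplitude convention of edge detection — so detected lengths are
unbiased. A much lower threshold (say a quarter of the mean) systematically
shortens every sweep by about half a smoothing width per edge (~27 kb
total), an 18% underestimate on a 151-kb sweep. Since observed sweep
densities run at 2–20% of chromosomal means, both thresholds *detect* the
same sweeps; 0.5 measures their extent without bias. Raising
`frac_threshold` can only grow a detected region (the below-threshold set
grows pointwise), which the tests assert as a monotonicity property.

The sweep table fixes the interval on one designated reference-cultivated
accession and then measures every accession's count and density over that
same interval — the layout in which such tables are published (one length
column, per-accession density columns).

## Gene-level diversity and effect classification

A gene is *covered* when at least `min_fraction = 0.8` of its span has mean
depth ≥ `min_depth = 4` in **every** accession supplied (intersection
rule): a cross-accession comparison is only meaningful where all accessions
could have been called. Published gene filters of the "at least 4 reads"
kind rarely specify the span fraction; 0.8 is a documented default, not a
reconstruction.

Gene density is SNPs per kb of the **gene span** (transcript-level extent)
by default, switchable to summed-CDS length, since "SNPs per kb of genes"
conventionally refers to the locus extent.

Coding effects are classified per SNP, independently against the reference
(no haplotype-aware multi-SNP codons): the genomic position is mapped
through the ordered CDS segments — on the minus strand through the reverse
complement, with segment order reversed — the affected codon is rebuilt
with the alternate allele substituted alone, and amino acids are compared
under the standard genetic code (`synonymous`, `nonsynonymous`,
`stop_gained`, `stop_lost`; SNPs in introns/UTRs are `noncoding`). Genes
whose summed CDS is not a multiple of 3 are kept for counting but excluded
from classification. A second, structurally independent implementation
(`classify_by_full_translation()`) rebuilds and translates the entire
mutant CDS with `Biostrings::translate()` and diffs the proteins; the test
suite requires exact agreement between the two routes over every possible
single-base substitution in simulated genes on both strands. Translation is
done with the plain codon table (`no.init.codon = TRUE`) so that a
start-codon change such as ATG→TTG is not silently translated as Met by the
initiator-codon convention.

A gene is flagged `low_diversity` when its density falls below a threshold
(default 1 SNP/kb — an analysis knob, not a published constant) in all
designated wild accessions: low diversity *in the wild relatives* over a
cultivated desert is what distinguishes pre-domestication selection from a
domestication bottleneck.

## The simulator

`simulate_snp_set()` places SNPs by an inhomogeneous Poisson process whose
rate is piecewise constant: a per-accession background (SNPs per kb) times
the product of the multipliers of any overlapping planted regions (deserts,
sweeps, centromeric suppression). Poisson placement, rather than a
coalescent, is a deliberate simplification: every statistic the pipeline
computes depends only on marginal SNP density, so a rate-based model keeps
the ground truth analytic — window counts are exactly Poisson with known
mean, and every recovery test has a closed-form reference distribution.
Alternate alleles are uniform over the three non-reference bases; at most
one SNP per position.

The default scenario (`default_sim_config()`) mirrors the study design the
package is aimed at: four accessions at backgrounds of 2.5, 2.4, 6.7 and
6.3 SNPs/kb (a cultivated line, a wild relative with a history of gene flow
from cultivation, and two isolated wild genomes) on two 5-Mb chromosomes;
one shared 500-kb desert spanning a centromere, at multiplier 0.02 in the
cultivated accession and 0.55 in the wild ones (deserts are only partially
conserved in the wild — the pre-domestication signature); and three sweeps
of 151, 357 and 488 kb (multiplier 0.02) in the cultivated accession only.
The desert's boundaries lie on the 100-kb scan grid: desert coordinates are
themselves defined from 100-kb windows, and a region deliberately placed
half-off the grid would leave mixed-rate edge windows that no threshold
detector can assign. Reference sequences are uniform random; genes are
ATG-initiated ORFs free of internal stops, in 1–3 CDS segments on either
strand; per-gene sequencing depth is drawn around a 6x mean with a
configurable fraction (default 0.35) of genes below the 4-read cut-off,
emulating a ~65% pass rate of a coverage filter.

What the simulator does **not** emulate — and what passing its tests
therefore does not establish about real data: linkage disequilibrium and
recombination-rate variation, mutation-rate heterogeneity (real windowed
counts are over-dispersed relative to Poisson; a negative-binomial `nb_size`
knob exists but defaults off and is not claimed to match any study),
alignment and calling artefacts, repeat-masking effects, and gradual sweep
shoulders (planted regions have sharp edges, so boundary-recovery results
are best-case).

## Numerical and degenerate-input choices

* Rounding of reported densities: half-up at the reported precision;
  internal arithmetic unrounded.
* Ties and boundaries: a SNP at position 100000 belongs to the first
  100-kb window, 100001 to the second; window membership is by closed
  interval.
* Degenerate t-test inputs (zero variance both sides) return t = 0 / p = 1
  on equal means and ±Inf / p = 0 otherwise.
* A centromere flank or locus flank extending past a chromosome end is
  truncated, flagged (warning or `truncated` field), and densities use the
  truncated length.
* `smooth_k` must be odd so the rolling mean is centred; even values are an
  error rather than a silent shift.
* The VCF reader fails fast with the line number on malformed lines and on
  positions beyond the declared chromosome length; records it drops by
  policy (indels, MNPs, unknown chromosomes, duplicate positions) are
  counted and reported.

## Problem sizes used by the test suite

The package's own test and verification runs use deliberately scaled
scenarios chosen to give each statistical check adequate power from
closed-form error bands: 100 seeded replicates on a 5-Mb chromosome for
desert recovery (binomial check against a ≥95% recovery requirement) and
sweep-length recovery (±10%, ≥90%); 200 replicates of a 10-Mb Poisson draw
for the simulator's mean calibration (3 standard errors); exhaustive
single-base substitution over 30-codon genes on both strands for effect
classification; and one full default scenario (2 × 5 Mb, four accessions,
143 genes, ~170k SNPs) through the whole pipeline.

## Known limitations

* Sweep extent is measured on smoothed windows against a fractional
  threshold; published sweep delimitations based on significance testing of
  mean reduction may place boundaries differently, and no per-sweep p-value
  is attached beyond the threshold rule.
* Desert calls inherit the scan resolution: boundaries are window-grid
  positions, so sub-window precision is not available.
* Effect classification is per-SNP; two SNPs in one codon are classified
  separately against the reference, as per-SNP counting conventions do.
* The coverage filter consumes mean depth per interval; base-resolution
  depth tracks are accepted but not required, and within-interval depth
  variation is invisible to it.
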