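# Shared fixtures, built in code. Heavier simulated objects are cached per
# test run so several test files can reuse them.

tiny_layout <- function(lens = c(chr1 = 5e5, chr2 = 3e5), centromeres = NULL) {
  genome_layout(lens, centromeres = centromeres)
}

make_callset <- function(layout, chrom, pos, accession_id = "acc",
                         ref = "A", alt = "C") {
  snp_callset(accession_id,
              data.frame(chrom = chrom, pos = pos,
                         ref = rep_len(ref, length(pos)),
                         alt = rep_len(alt, length(pos))),
              layout)
}

# Welch statistic from the textbook formula, independent of stats::t.test
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# small reference shared across files: 2 x 500 kb, 12 genes
shared_ref_cache <- new.env()
shared_small_ref <- function() {
  if (is.null(shared_ref_cache$ref)) {
    lay <- genome_layout(c(chr1 = 5e5, chr2 = 5e5))
    cfg <- simulation_config(lay, accessions = list(a = diversity_profile(3)),
                             n_genes = 12, cds_length_range = c(150, 600),
                             seed = 101)
    shared_ref_cache$ref <- c(simulate_reference(cfg, seed = 101),
                              list(layout = lay, config = cfg))
  }
  shared_ref_cache$ref
}

# genomic positions covered by a gene's CDS
cds_positions <- function(gene) {
  unlist(apply(gene$cds_segments, 1, function(s) seq(s[1], s[2])))
}

expect_same_callset <- function(a, b) {
  expect_equal(a$snps$chrom, b$snps$chrom)
  expect_equal(a$snps$pos, b$snps$pos)
  expect_equal(a$snps$ref, b$snps$ref)
  expect_equal(a$snps$alt, b$snps$alt)
}
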