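# hand-built two-gene reference: the same CDS planted on both strands.
# chr1: +strand gene at 11..40 (single exon), chr2: -strand mirror image.
hand_ref <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cds <- "ATGGCTAGCCTTAAGGATCTGCGATGTTGA"  # M A S L K D L R C *
    pad5 <- "CCCCCCCCCC"; pad3 <- "GGGGGGGGGG"
    plus_chrom <- paste0(pad5, cds, pad3)
    minus_chrom <- paste0(pad5, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds))), pad3)
    seqs <- Biostrings::DNAStringSet(c(chr1 = plus_chrom, chr2 = minus_chrom))
    genes <- list(
      plus = gene_model("plus", "chr1", "+", cbind(11, 40), c(11, 40)),
      minus = gene_model("minus", "chr2", "-", cbind(11, 40), c(11, 40)))
    cache <<- list(seqs = seqs, genes = genes)
    cache
  }
})

test_that("codon-level classification follows the genetic code", {
  h <- hand_ref()
  g <- h$genes$plus
  # codon 2 is GCT (Ala) at positions 14-16
  expect_equal(classify_snp_effect(list(chrom = "chr1", pos = 16, ref = "T",
                                        alt = "A"), g, h$seqs),
               "synonymous")   # GCT -> GCA, Ala -> Ala
  expect_equal(classify_snp_effect(list(chrom = "chr1", pos = 14, ref = "G",
                                        alt = "A"), g, h$seqs),
               "nonsynonymous")  # GCT -> ACT, Ala -> Thr
  # codon 5 AAG (Lys) at 23-25: A->T at pos 23 gives TAG stop
  expect_equal(classify_snp_effect(list(chrom = "chr1", pos = 23, ref = "A",
                                        alt = "T"), g, h$seqs),
               "stop_gained")
  # terminal stop TGA at 38-40: G->C gives TCA (Ser)
  expect_equal(classify_snp_effect(list(chrom = "chr1", pos = 39, ref = "G",
                                        alt = "C"), g, h$seqs),
               "stop_lost")
  # outside the CDS
  expect_equal(classify_snp_effect(list(chrom = "chr1", pos = 5, ref = "C",
                                        alt = "T"), g, h$seqs),
               "noncoding")
})

test_that("classification errors on reference mismatch, warns on broken CDS", {
  h <- hand_ref()
  expect_error(classify_snp_effect(list(chrom = "chr1", pos = 16, ref = "G",
                                        alt = "A"), h$genes$plus, h$seqs),
               "reference mismatch at chr1:16")
  broken <- gene_model("b", "chr1", "+", cbind(11, 39), c(11, 40))
  expect_true(broken$cds_incomplete)
  expect_warning(
    eff <- classify_snp_effect(list(chrom = "chr1", pos = 16, ref = "T",
                                    alt = "A"), broken, h$seqs),
    "not divisible by 3")
  expect_equal(eff, "noncoding")
})

test_that("strand mirror images classify identically", {
  h <- hand_ref()
  chrom_len <- 50
  for (pos in 11:40) {
    ref_b <- as.character(Biostrings::subseq(h$seqs$chr1, pos, pos))
    mirror_pos <- chrom_len - pos + 1
    mirror_ref <- as.character(Biostrings::subseq(h$seqs$chr2,
                                                  mirror_pos, mirror_pos))
    for (alt in setdiff(c("A", "C", "G", "T"), ref_b)) {
      e_plus <- classify_snp_effect(list(chrom = "chr1", pos = pos,
                                         ref = ref_b, alt = alt),
                                    h$genes$plus, h$seqs)
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      e_minus <- classify_snp_effect(list(chrom = "chr2", pos = mirror_pos,
                                          ref = mirror_ref, alt = comp[[alt]]),
                                     h$genes$minus, h$seqs)
      expect_equal(e_minus, e_plus)
    }
  }
})

test_that("classification agrees with full-translation on every substitution", {
  ref <- shared_small_ref()
  genes <- ref$genes[1:3]
  for (g in genes) {
    for (pos in cds_positions(g)) {
      rb <- as.character(Biostrings::subseq(ref$sequences[[g$chrom]], pos, pos))
      for (alt in setdiff(c("A", "C", "G", "T"), rb)) {
        snp <- list(chrom = g$chrom, pos = pos, ref = rb, alt = alt)
        expect_identical(classify_snp_effect(snp, g, ref$sequences),
                         classify_by_full_translation(snp, g, ref$sequences))
      }
    }
  }
})

test_that("coverage filter applies the all-accession intersection rule", {
  lay <- genome_layout(c(chr1 = 10000))
  genes <- list(g1 = gene_model("g1", "chr1", "+", cbind(1001, 2000),
                                c(1001, 2000)),
                g2 = gene_model("g2", "chr1", "+", cbind(5001, 5900),
                                c(5001, 5900)))
  cov_hi <- data.frame(chrom = "chr1", start = 1, end = 10000, mean_depth = 10)
  part <- gene_coverage_filter(genes, cov_hi)
  expect_length(part$covered, 2)

  cov_lo <- data.frame(chrom = "chr1", start = c(1, 5001, 5901),
                       end = c(5000, 5900, 10000), mean_depth = c(10, 2, 10))
  part2 <- gene_coverage_filter(genes, list(accA = cov_hi, accB = cov_lo))
  expect_equal(names(part2$covered), "g1")
  expect_equal(names(part2$uncovered), "g2")

  # partial low coverage: 15% of g1 below depth 4 still passes at 0.8
  cov_part <- data.frame(chrom = "chr1", start = c(1, 1001, 1151),
                         end = c(1000, 1150, 10000), mean_depth = c(10, 1, 10))
  expect_length(gene_coverage_filter(genes, cov_part)$covered, 2)
  expect_length(gene_coverage_filter(genes, cov_part,
                                     min_fraction = 0.9)$covered, 1)

  no_data <- data.frame(chrom = "chr9", start = 1, end = 10, mean_depth = 5)
  warns <- capture_warnings(part3 <- gene_coverage_filter(genes, no_data))
  expect_length(warns, 2)   # one warning per uncovered gene
  expect_match(warns, "no coverage", all = TRUE)
  expect_length(part3$covered, 0)
})

test_that("gene_report densities, summaries and flags are self-consistent", {
  ref <- shared_small_ref()
  lay <- ref$layout
  cult <- simulate_snp_set(diversity_profile(2.5), lay, ref$sequences,
                           seed = 501, accession_id = "cult")
  wild <- simulate_snp_set(diversity_profile(10), lay, ref$sequences,
                           seed = 502, accession_id = "wild")
  rep <- gene_report(list(cult = cult, wild = wild), ref$genes, ref$sequences,
                     wild_accessions = "wild")
  tab <- rep$genes
  expect_equal(nrow(tab), 2 * length(ref$genes))
  expect_true(all(tab$ns_snp_count + tab$syn_snp_count <= tab$snp_count))
  expect_equal(tab$snps_per_kb, tab$snp_count / tab$gene_length_kb)

  # summary equals brute-force recomputation from the rows
  for (acc in c("cult", "wild")) {
    rows <- tab[tab$accession_id == acc, ]
    s <- rep$summary[rep$summary$accession_id == acc, ]
    expect_equal(s$mean_snps_per_kb, mean(rows$snps_per_kb))
    expect_equal(s$mean_ns_snps_per_kb,
                 mean(rows$ns_snp_count / rows$gene_length_kb))
  }

  # per-gene counts agree with the simulator's independent truth
  truth <- desertscan:::gene_effect_truth(list(cult = cult), ref$genes,
                                          ref$sequences)
  mine <- tab[tab$accession_id == "cult", ]
  expect_equal(mine$snp_count, truth$snp_count[match(mine$gene_id, truth$gene_id)])
  expect_equal(mine$ns_snp_count,
               truth$ns_snp_count[match(mine$gene_id, truth$gene_id)])

  # low_diversity is defined by the wild accessions only
  expect_equal(unique(tab$low_diversity[tab$gene_id %in%
    tab$gene_id[tab$accession_id == "wild" & tab$snps_per_kb >= 1]]), FALSE)
})

test_that("no SNPs means zero densities and universal low-diversity flags", {
  ref <- shared_small_ref()
  empty <- snp_callset("none", data.frame(), ref$layout)
  rep <- gene_report(list(none = empty), ref$genes, ref$sequences)
  expect_true(all(rep$genes$snps_per_kb == 0))
  expect_true(all(rep$genes$low_diversity))
})

test_that("region restriction is additive with its complement", {
  ref <- shared_small_ref()
  cs <- simulate_snp_set(diversity_profile(8), ref$layout, ref$sequences,
                         seed = 77, accession_id = "a")
  whole <- gene_report(list(a = cs), ref$genes, ref$sequences)
  left <- gene_report(list(a = cs), ref$genes, ref$sequences,
                      region = list(chrom = "chr1", start = 1, end = 5e5))
  right <- gene_report(list(a = cs), ref$genes, ref$sequences,
                       region = list(chrom = "chr2", start = 1, end = 5e5))
  expect_setequal(c(left$genes$gene_id, right$genes$gene_id),
                  whole$genes$gene_id)
  expect_equal(sum(left$genes$snp_count) + sum(right$genes$snp_count),
               sum(whole$genes$snp_count))
})
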