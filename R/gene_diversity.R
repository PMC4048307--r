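# Gene-level diversity: coverage filtering, synonymous/nonsynonymous
# classification of coding SNPs, and per-gene density reports.

# spliced CDS sequence of a gene in reading order (5'->3' of the mRNA)
cds_sequence <- function(gene, ref_seqs) {
  chrom_seq <- ref_seqs[[gene$chrom]]
  if (is.null(chrom_seq)) stop("reference has no sequence for ", gene$chrom)
  parts <- apply(gene$cds_segments, 1, function(seg)
    as.character(Biostrings::subseq(chrom_seq, seg[1], seg[2])))
  s <- Biostrings::DNAString(paste(parts, collapse = ""))
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

translate_codon <- function(codon) Biostrings::GENETIC_CODE[[codon]]

#' Classify the coding effect of a SNP on a gene
#'
#' Maps the genomic position through the gene's CDS segments (strand-aware:
#' on the minus strand the CDS is read on the reverse complement, segments in
#' 3'->5' genomic order), rebuilds the affected codon with the alternate
#' allele substituted alone, and compares amino acids under the standard
#' genetic code. SNPs outside the CDS (introns, UTRs within the gene span)
#' are `noncoding`; genes flagged with a CDS length that is not a multiple of
#' 3 yield `noncoding` with a warning.
#'
#' @param snp one-row data.frame or list with chrom, pos, ref, alt.
#' @param gene a [gene_model()] on the same chromosome.
#' @param ref_seqs reference [Biostrings::DNAStringSet] named by chromosome;
#'   the base at `snp$pos` must equal `snp$ref` (an error otherwise).
#' @param cds optional precomputed `as.character(cds_sequence)` of the gene,
#'   to avoid rebuilding it when classifying many SNPs of one gene.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stop_gained"`,
#'   `"stop_lost"`, `"noncoding"`.
#' @examples
#' \dontrun{
#' classify_snp_effect(list(chrom = "chr1", pos = 6, ref = "T", alt = "A"),
#'                     gene, ref_seqs)
#' }
#' @export
classify_snp_effect <- function(snp, gene, ref_seqs, cds = NULL) {
  if (snp$chrom != gene$chrom) stop("SNP and gene on different chromosomes")
  ref_base <- as.character(Biostrings::subseq(ref_seqs[[gene$chrom]],
                                              snp$pos, snp$pos))
  if (ref_base != snp$ref)
    stop(sprintf("reference mismatch at %s:%d: FASTA has %s, record has %s",
                 snp$chrom, as.integer(snp$pos), ref_base, snp$ref))
  if (gene$cds_incomplete) {
    warning("gene ", gene$gene_id,
            " has CDS length not divisible by 3; SNP treated as noncoding")
    return("noncoding")
  }
  seg <- gene$cds_segments
  in_seg <- which(snp$pos >= seg[, 1] & snp$pos <= seg[, 2])
  if (length(in_seg) == 0) return("noncoding")
  widths <- seg[, 2] - seg[, 1] + 1
  off_plus <- (if (in_seg > 1) sum(widths[seq_len(in_seg - 1)]) else 0) +
    snp$pos - seg[in_seg, 1] + 1
  cds_pos <- if (gene$strand == "+") off_plus else gene$cds_length - off_plus + 1
  if (is.null(cds)) cds <- as.character(cds_sequence(gene, ref_seqs))
  alt_cds_base <- if (gene$strand == "+") snp$alt else complement_base(snp$alt)
  codon_i <- ceiling(cds_pos / 3)
  within <- cds_pos - (codon_i - 1) * 3
  ref_codon <- substr(cds, (codon_i - 1) * 3 + 1, codon_i * 3)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_cds_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (ref_aa == alt_aa) return("synonymous")
  if (alt_aa == "*") return("stop_gained")
  if (ref_aa == "*") return("stop_lost")
  "nonsynonymous"
}

# fraction of a gene span covered at >= min_depth under one coverage track
covered_fraction <- function(gene, coverage, min_depth) {
  cov <- coverage[coverage$chrom == gene$chrom, , drop = FALSE]
  if (nrow(cov) == 0) return(NA_real_)
  ov_start <- pmax(cov$start, gene$gene_span[1])
  ov_end <- pmin(cov$end, gene$gene_span[2])
  w <- pmax(0, ov_end - ov_start + 1)
  if (sum(w) == 0) return(NA_real_)
  sum(w[cov$mean_depth >= min_depth]) / (gene$gene_span[2] - gene$gene_span[1] + 1)
}

#' Partition genes by sequencing coverage
#'
#' A gene is "covered" when at least `min_fraction` of its span has depth
#' `>= min_depth` in EVERY accession's coverage track (intersection rule:
#' comparisons across accessions only make sense where all of them were
#' sequenced deep enough). Genes with no coverage data over their span are
#' uncovered, with a warning.
#'
#' @param genes named list of [gene_model()] objects.
#' @param coverage a coverage track data.frame (chrom, start, end,
#'   mean_depth), or a named list of such tracks, one per accession.
#' @param min_depth depth cut-off (default 4 reads).
#' @param min_fraction minimum covered fraction of the gene span (default 0.8).
#' @return list with `covered` and `uncovered` (named lists of gene models).
#' @export
gene_coverage_filter <- function(genes, coverage, min_depth = 4,
                                 min_fraction = 0.8) {
  tracks <- if (is.data.frame(coverage)) list(coverage) else coverage
  ok <- vapply(genes, function(g) {
    fr <- vapply(tracks, covered_fraction, 0, gene = g, min_depth = min_depth)
    if (anyNA(fr)) {
      warning("gene ", g$gene_id, " has no coverage data; treated as uncovered")
      return(FALSE)
    }
    all(fr >= min_fraction)
  }, logical(1))
  list(covered = genes[ok], uncovered = genes[!ok])
}

#' Per-gene diversity report across accessions
#'
#' For every covered gene and every accession: SNP count over the gene span,
#' density in SNPs per kb of span, and synonymous/nonsynonymous counts for
#' coding SNPs. A gene is flagged `low_diversity` when its density is below
#' `low_diversity_threshold` in all the accessions named in
#' `wild_accessions` (all accessions when NULL) — the signature of
#' conservation that predates the accessions' divergence.
#'
#' @param callsets named list of [snp_callset()] objects.
#' @param genes named list of [gene_model()] objects.
#' @param ref_seqs reference [Biostrings::DNAStringSet] for effect
#'   classification.
#' @param coverage coverage track(s) for [gene_coverage_filter()], or NULL to
#'   skip coverage filtering.
#' @param region optional list/one-row data.frame (chrom, start, end):
#'   restrict to genes whose span overlaps it.
#' @param wild_accessions accession names whose joint low density defines
#'   `low_diversity`.
#' @param low_diversity_threshold SNPs/kb cut-off for the flag (default 1.0).
#' @param min_depth,min_fraction coverage-filter parameters.
#' @param length_basis `"span"` (default) measures density per kb of the gene
#'   span; `"cds"` per kb of summed CDS.
#' @return list with `genes` (one row per covered gene x accession: gene_id,
#'   accession_id, covered, snp_count, gene_length_kb, snps_per_kb,
#'   ns_snp_count, syn_snp_count, low_diversity), `summary` (per-accession
#'   mean SNPs/kb and mean nsSNPs/kb over covered genes), and `uncovered`
#'   (gene ids that failed the coverage filter).
#' @export
gene_report <- function(callsets, genes, ref_seqs, coverage = NULL,
                        region = NULL, wild_accessions = NULL,
                        low_diversity_threshold = 1.0,
                        min_depth = 4, min_fraction = 0.8,
                        length_basis = c("span", "cds")) {
  length_basis <- match.arg(length_basis)
  if (!is.null(region)) {
    genes <- Filter(function(g) g$chrom == region$chrom[1] &&
                      g$gene_span[1] <= region$end[1] &&
                      g$gene_span[2] >= region$start[1], genes)
  }
  uncovered <- character()
  if (!is.null(coverage)) {
    part <- gene_coverage_filter(genes, coverage, min_depth, min_fraction)
    uncovered <- names(part$uncovered)
    genes <- part$covered
  }
  rows <- list()
  for (gid in names(genes)) {
    g <- genes[[gid]]
    len_kb <- if (length_basis == "span") gene_span_length_kb(g) else g$cds_length / 1000
    for (acc in names(callsets)) {
      snps <- callsets[[acc]]$snps
      hit <- snps[snps$chrom == g$chrom & snps$pos >= g$gene_span[1] &
                    snps$pos <= g$gene_span[2], , drop = FALSE]
      eff <- if (nrow(hit) && !g$cds_incomplete) {
        cds_str <- as.character(cds_sequence(g, ref_seqs))
        vapply(seq_len(nrow(hit)), function(i)
          classify_snp_effect(hit[i, ], g, ref_seqs, cds = cds_str), "")
      } else character()
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, accession_id = acc, covered = TRUE,
        snp_count = nrow(hit), gene_length_kb = len_kb,
        snps_per_kb = nrow(hit) / len_kb,
        ns_snp_count = sum(eff %in% c("nonsynonymous", "stop_gained", "stop_lost")),
        syn_snp_count = sum(eff == "synonymous"))
    }
  }
  if (length(rows) == 0) {
    return(list(genes = data.frame(), summary = data.frame(),
                uncovered = uncovered))
  }
  tab <- do.call(rbind, rows)
  wild <- if (is.null(wild_accessions)) names(callsets) else wild_accessions
  low_by_gene <- vapply(split(tab, tab$gene_id), function(d)
    all(d$snps_per_kb[d$accession_id %in% wild] < low_diversity_threshold),
    logical(1))
  tab$low_diversity <- low_by_gene[tab$gene_id]
  summ <- do.call(rbind, lapply(split(tab, tab$accession_id), function(d)
    data.frame(accession_id = d$accession_id[1],
               n_genes = nrow(d),
               mean_snps_per_kb = mean(d$snps_per_kb),
               mean_ns_snps_per_kb = mean(d$ns_snp_count / d$gene_length_kb),
               n_low_diversity = sum(d$low_diversity))))
  rownames(tab) <- rownames(summ) <- NULL
  list(genes = tab, summary = summ, uncovered = uncovered)
}
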