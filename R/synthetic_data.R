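# Synthetic multi-accession SNP landscapes with planted low-diversity
# regions. SNPs are placed by an inhomogeneous Poisson process whose rate is
# piecewise constant (base rate x product of overlapping region multipliers),
# which keeps every downstream expectation analytic: window counts are
# Poisson with known mean, so recovery tests have exact reference
# distributions. No linkage or coalescent structure is modelled.

#' Piecewise-constant SNP-rate profile for one accession
#'
#' @param base_rate background SNP rate in SNPs per kb.
#' @param modifiers data.frame with columns chrom, start, end, multiplier
#'   (>= 0) and label (e.g. "desert", "sweep", "centromere"); overlapping
#'   modifiers multiply.
#' @param nb_size optional negative-binomial size parameter; when set,
#'   per-segment SNP counts are drawn NB with the Poisson mean, adding
#'   overdispersion. NULL (default) keeps the pure Poisson model.
#' @return object of class `diversity_profile`.
#' @export
diversity_profile <- function(base_rate, modifiers = NULL, nb_size = NULL) {
  stopifnot(base_rate >= 0)
  if (is.null(modifiers))
    modifiers <- data.frame(chrom = character(), start = numeric(),
                            end = numeric(), multiplier = numeric(),
                            label = character())
  stopifnot(all(c("chrom", "start", "end", "multiplier", "label") %in% names(modifiers)))
  if (any(modifiers$multiplier < 0)) stop("multipliers must be >= 0")
  if (any(modifiers$start > modifiers$end)) stop("modifier with start > end")
  structure(list(base_rate = base_rate, modifiers = modifiers,
                 nb_size = nb_size),
            class = "diversity_profile")
}

#' Simulation configuration
#'
#' @param layout a [genome_layout()].
#' @param accessions named list of [diversity_profile()] objects.
#' @param n_genes number of genes to plant.
#' @param cds_length_range (min, max) total CDS length in bp; rounded to
#'   whole codons.
#' @param coverage_mean mean sequencing depth for well-covered regions.
#' @param low_coverage_gene_fraction fraction of genes assigned depth < 4.
#' @param seed integer master seed; a fixed seed gives byte-identical output
#'   files.
#' @export
simulation_config <- function(layout, accessions, n_genes = 143,
                              cds_length_range = c(300, 1500),
                              coverage_mean = 6,
                              low_coverage_gene_fraction = 0.35,
                              seed = 1) {
  stopifnot(inherits(layout, "genome_layout"), length(accessions) >= 1,
            !is.null(names(accessions)),
            low_coverage_gene_fraction >= 0, low_coverage_gene_fraction <= 1,
            cds_length_range[1] >= 9, cds_length_range[2] >= cds_length_range[1])
  for (p in accessions) {
    stopifnot(inherits(p, "diversity_profile"))
    if (nrow(p$modifiers)) {
      len <- chrom_length(layout, p$modifiers$chrom)
      if (any(p$modifiers$start < 1 | p$modifiers$end > len))
        stop("modifier interval outside chromosome bounds")
    }
  }
  structure(list(layout = layout, accessions = accessions, n_genes = n_genes,
                 cds_length_range = cds_length_range,
                 coverage_mean = coverage_mean,
                 low_coverage_gene_fraction = low_coverage_gene_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default demonstration scenario
#'
#' Two 5-Mb chromosomes with centromeres at their midpoints and four
#' accessions emulating one resequencing-study design: a cultivated genome
#' (2.5 SNPs/kb against the reference), a related wild genome that has
#' exchanged genes with cultivation (2.4 SNPs/kb), and two isolated wild
#' genomes (6.7 and 6.3 SNPs/kb). One shared 500-kb polymorphism desert
#' spans the chr1 centromere: multiplier 0.02 in the cultivated accession
#' and 0.55 in the wild ones (deserts are partially conserved in the wild —
#' the pre-domestication signature). Three sweeps of 151, 357 and 488 kb
#' (multiplier 0.02) are planted around loci on chr2 in the cultivated
#' accession only.
#'
#' @param seed master seed.
#' @return a [simulation_config()]; the planted loci table is attached as
#'   attribute `"loci"`.
#' @export
default_sim_config <- function(seed = 1) {
  layout <- genome_layout(c(chr1 = 5e6, chr2 = 5e6),
                          centromeres = c(chr1 = 2.5e6, chr2 = 2.5e6))
  # desert boundaries fall on the 100-kb scan grid, as real desert calls do
  # (they are delimited from 100-kb windows in the first place)
  desert <- function(mult)
    data.frame(chrom = "chr1", start = 2200001, end = 2700000,
               multiplier = mult, label = "desert")
  sweeps <- data.frame(
    chrom = "chr2",
    start = c(1e6 - 75500, 2.5e6 - 178500, 4e6 - 244000) + 1,
    end = c(1e6 + 75500, 2.5e6 + 178500, 4e6 + 244000),
    multiplier = 0.02,
    label = "sweep")
  cfg <- simulation_config(
    layout,
    accessions = list(
      cultivated = diversity_profile(2.5, rbind(desert(0.02), sweeps)),
      wild_asian = diversity_profile(2.4, desert(0.55)),
      wild_australian = diversity_profile(6.7, desert(0.55)),
      wild_meridionalis = diversity_profile(6.3, desert(0.55))),
    seed = seed)
  attr(cfg, "loci") <- data.frame(name = c("locusA", "locusB", "locusC"),
                                  chrom = "chr2",
                                  position = c(1e6, 2.5e6, 4e6))
  cfg
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

random_cds <- function(n_codons) {
  sense <- setdiff(all_codons(), STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1))
}

# split a CDS string into n_seg genomic segments of width >= min_part
split_cds <- function(cds, n_seg, min_part = 30) {
  n <- nchar(cds)
  if (n_seg == 1) return(cds)
  repeat {
    cuts <- sort(sample(seq(min_part, n - min_part), n_seg - 1))
    w <- diff(c(0, cuts, n))
    if (all(w >= min_part)) break
  }
  substring(cds, c(1, cuts + 1), c(cuts, n))
}

#' Simulate a reference genome with planted gene models
#'
#' Uniform-random sequence per chromosome; `n_genes` non-overlapping genes
#' with 1-3 CDS segments each, ATG-initiated open reading frames free of
#' internal stop codons and ending in a stop, on both strands.
#'
#' @param config a [simulation_config()].
#' @param seed seed for this stage (defaults to `config$seed`).
#' @return list with `sequences` ([Biostrings::DNAStringSet]) and `genes`
#'   (named list of [gene_model()]).
#' @export
simulate_reference <- function(config, seed = config$seed) {
  set.seed(seed)
  layout <- config$layout
  seqs <- lapply(layout$chromosomes$length_bp, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  names(seqs) <- layout$chromosomes$name

  genes <- list()
  occupied <- lapply(seqs, function(x) matrix(numeric(), ncol = 2))
  if (config$n_genes > 0) {
    for (i in seq_len(config$n_genes)) {
      placed <- FALSE
      for (attempt in 1:200) {
        chrom <- sample(layout$chromosomes$name, 1)
        clen <- chrom_length(layout, chrom)
        n_codons <- floor(stats::runif(1, config$cds_length_range[1],
                                       config$cds_length_range[2]) / 3)
        cds <- random_cds(n_codons)
        n_seg <- sample(1:3, 1)
        if (nchar(cds) < n_seg * 60) n_seg <- 1
        parts <- split_cds(cds, n_seg)
        introns <- if (n_seg > 1) sample(50:500, n_seg - 1, replace = TRUE) else integer()
        span_len <- sum(nchar(parts)) + sum(introns)
        start <- floor(stats::runif(1, 1, clen - span_len))
        end <- start + span_len - 1
        occ <- occupied[[chrom]]
        if (nrow(occ) && any(start <= occ[, 2] + 100 & end >= occ[, 1] - 100)) next
        strand <- sample(c("+", "-"), 1)
        widths <- nchar(parts)
        if (strand == "-") {
          # genomic left-to-right content is the reverse complement of the
          # mRNA; genomic segment widths are the mRNA part widths reversed
          g <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
          widths <- rev(widths)
          ends_cum <- cumsum(widths)
          contents <- substring(g, c(1, ends_cum[-n_seg] + 1), ends_cum)
        } else {
          contents <- parts
        }
        seg_start <- start + c(0, cumsum(widths[-n_seg] + introns))
        seg_end <- seg_start + widths - 1
        gid <- sprintf("gene%03d", i)
        genes[[gid]] <- gene_model(gid, chrom, strand,
                                   cbind(seg_start, seg_end), c(start, end))
        attr(genes[[gid]], "seg_contents") <- contents
        occupied[[chrom]] <- rbind(occ, c(start, end))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", config$n_genes, " non-overlapping genes; ",
             "use fewer or shorter genes")
    }
  }
  # splice the CDS content into the chromosome sequences
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  for (gid in names(genes)) {
    g <- genes[[gid]]
    at <- IRanges::IRanges(g$cds_segments[, 1], g$cds_segments[, 2])
    dna[[g$chrom]] <- Biostrings::replaceAt(
      dna[[g$chrom]], at, Biostrings::DNAStringSet(attr(g, "seg_contents")))
    attr(genes[[gid]], "seg_contents") <- NULL
  }
  list(sequences = dna, genes = genes)
}

# piecewise-constant rate segments for one chromosome of a profile
rate_segments <- function(profile, chrom, chrom_len) {
  mods <- profile$modifiers[profile$modifiers$chrom == chrom, , drop = FALSE]
  bounds <- sort(unique(c(1, chrom_len + 1, mods$start, mods$end + 1)))
  bounds <- bounds[bounds >= 1 & bounds <= chrom_len + 1]
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1] - 1
  mult <- vapply(seq_along(starts), function(i) {
    cover <- mods$start <= starts[i] & mods$end >= ends[i]
    prod(mods$multiplier[cover])
  }, 0)
  data.frame(start = starts, end = ends, multiplier = mult)
}

#' Simulate one accession's SNP call set
#'
#' Positions are drawn from an inhomogeneous Poisson process with rate
#' `base_rate x product of overlapping multipliers` (piecewise constant), at
#' most one SNP per position; the alternate allele is uniform over the three
#' non-reference bases.
#'
#' @param profile a [diversity_profile()].
#' @param layout a [genome_layout()].
#' @param reference [Biostrings::DNAStringSet] named by chromosome.
#' @param seed integer seed.
#' @param accession_id name for the call set.
#' @return a [snp_callset()].
#' @export
simulate_snp_set <- function(profile, layout, reference, seed,
                             accession_id = "sim") {
  set.seed(seed)
  recs <- list()
  for (ci in seq_len(nrow(layout$chromosomes))) {
    chrom <- layout$chromosomes$name[ci]
    clen <- layout$chromosomes$length_bp[ci]
    segs <- rate_segments(profile, chrom, clen)
    pos <- numeric()
    for (i in seq_len(nrow(segs))) {
      width <- segs$end[i] - segs$start[i] + 1
      mu <- profile$base_rate / 1000 * segs$multiplier[i] * width
      n <- if (is.null(profile$nb_size)) stats::rpois(1, mu)
           else stats::rnbinom(1, size = profile$nb_size, mu = mu)
      n <- min(n, width)
      if (n > 0) pos <- c(pos, segs$start[i] - 1 + sample.int(width, n))
    }
    if (length(pos) == 0) next
    pos <- sort(pos)
    chrom_str <- as.character(reference[[chrom]])
    ref <- substring(chrom_str, pos, pos)
    bases <- c("A", "C", "G", "T")
    alt_options <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                         c("A", "C", "T"), c("A", "C", "G"))
    alt <- alt_options[cbind(match(ref, bases),
                             sample.int(3, length(pos), replace = TRUE))]
    recs[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt)
  }
  snps <- if (length(recs)) do.call(rbind, recs) else data.frame()
  snp_callset(accession_id, snps, layout)
}

#' Simulate a coverage track over planted genes
#'
#' Each gene's span gets a mean depth drawn around `coverage_mean` (never
#' below 4), except a randomly chosen fraction `low_coverage_gene_fraction`
#' of genes which get depth uniform on (0.5, 3.5) — i.e. below a 4-read
#' cut-off. Intergenic tiles sit at `coverage_mean`.
#'
#' @param config a [simulation_config()].
#' @param genes named list of [gene_model()] from [simulate_reference()].
#' @param seed seed for this stage.
#' @return coverage track data.frame (chrom, start, end, mean_depth).
#' @export
simulate_coverage <- function(config, genes, seed = config$seed + 1L) {
  set.seed(seed)
  layout <- config$layout
  n <- length(genes)
  low <- if (n) stats::runif(n) < config$low_coverage_gene_fraction else logical()
  depth <- numeric(n)
  depth[!low] <- pmax(4, stats::rnorm(sum(!low), config$coverage_mean,
                                      config$coverage_mean / 5))
  depth[low] <- stats::runif(sum(low), 0.5, 3.5)
  gene_tab <- data.frame(
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, function(g) g$gene_span[1], 0),
    end = vapply(genes, function(g) g$gene_span[2], 0),
    mean_depth = depth)
  rows <- list()
  for (ci in seq_len(nrow(layout$chromosomes))) {
    chrom <- layout$chromosomes$name[ci]
    clen <- layout$chromosomes$length_bp[ci]
    gt <- gene_tab[gene_tab$chrom == chrom, , drop = FALSE]
    gt <- gt[order(gt$start), , drop = FALSE]
    cursor <- 1
    for (i in seq_len(nrow(gt))) {
      if (gt$start[i] > cursor)
        rows[[length(rows) + 1]] <- data.frame(chrom = chrom, start = cursor,
                                               end = gt$start[i] - 1,
                                               mean_depth = config$coverage_mean)
      rows[[length(rows) + 1]] <- gt[i, ]
      cursor <- gt$end[i] + 1
    }
    if (cursor <= clen)
      rows[[length(rows) + 1]] <- data.frame(chrom = chrom, start = cursor,
                                             end = clen,
                                             mean_depth = config$coverage_mean)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coverage_track", "data.frame")
  out
}

#' Classify a coding SNP by translating the full mutant CDS
#'
#' Reference implementation used to record simulation ground truth and to
#' validate [classify_snp_effect()]: the whole CDS is rebuilt with the
#' alternate allele substituted, both CDS are translated with
#' [Biostrings::translate()], and the two protein sequences compared.
#'
#' @inheritParams classify_snp_effect
#' @export
classify_by_full_translation <- function(snp, gene, ref_seqs) {
  if (gene$cds_incomplete) return("noncoding")
  seg <- gene$cds_segments
  in_seg <- which(snp$pos >= seg[, 1] & snp$pos <= seg[, 2])
  if (length(in_seg) == 0) return("noncoding")
  # work on the gene-local sequence; coordinates shifted to span-relative
  off <- gene$gene_span[1] - 1
  local_seq <- Biostrings::subseq(ref_seqs[[gene$chrom]],
                                  gene$gene_span[1], gene$gene_span[2])
  local_gene <- gene_model(gene$gene_id, gene$chrom, gene$strand,
                           cbind(seg[, 1] - off, seg[, 2] - off),
                           c(1, gene$gene_span[2] - off))
  mutant <- Biostrings::replaceAt(local_seq,
                                  IRanges::IRanges(snp$pos - off, snp$pos - off),
                                  snp$alt)
  ref_env <- stats::setNames(list(local_seq), gene$chrom)
  mut_env <- stats::setNames(list(mutant), gene$chrom)
  # no.init.codon: apply the plain codon table, so a start-codon change
  # (e.g. ATG->TTG) is not masked by initiator-codon translation to Met
  p_ref <- as.character(Biostrings::translate(cds_sequence(local_gene, ref_env),
                                              no.init.codon = TRUE))
  p_alt <- as.character(Biostrings::translate(cds_sequence(local_gene, mut_env),
                                              no.init.codon = TRUE))
  if (p_ref == p_alt) return("synonymous")
  i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  ref_aa <- substr(p_ref, i, i)
  alt_aa <- substr(p_alt, i, i)
  if (alt_aa == "*") return("stop_gained")
  if (ref_aa == "*") return("stop_lost")
  "nonsynonymous"
}

#' Simulate a full multi-accession data set and write it to disk
#'
#' Runs [simulate_reference()], [simulate_snp_set()] per accession and
#' [simulate_coverage()], records the planted truth, and writes: `ref.fa`,
#' `genes.gff3`, `layout.tsv`, `<accession>.vcf` per accession,
#' `coverage.tsv`, and under `truth/`: one BED of planted regions per
#' accession plus `gene_effects.tsv` with true per-gene effect counts (from
#' [classify_by_full_translation()]). A fixed seed reproduces every file
#' byte for byte.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @return list with layout, sequences, genes, callsets, coverage, truth and
#'   (when written) file paths.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  ref <- simulate_reference(config, seed = config$seed)
  coverage <- simulate_coverage(config, ref$genes, seed = config$seed + 1L)
  callsets <- list()
  acc_names <- names(config$accessions)
  for (i in seq_along(acc_names)) {
    callsets[[acc_names[i]]] <- simulate_snp_set(
      config$accessions[[i]], config$layout, ref$sequences,
      seed = config$seed + 100L + i, accession_id = acc_names[i])
  }
  regions <- do.call(rbind, lapply(acc_names, function(a) {
    m <- config$accessions[[a]]$modifiers
    if (nrow(m) == 0) return(NULL)
    cbind(accession_id = a, m)
  }))
  effects <- gene_effect_truth(callsets, ref$genes, ref$sequences)
  truth <- list(regions = regions, gene_effects = effects)
  out <- list(layout = config$layout, sequences = ref$sequences,
              genes = ref$genes, callsets = callsets, coverage = coverage,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "ref.fa"),
      gff3 = file.path(out_dir, "genes.gff3"),
      layout = file.path(out_dir, "layout.tsv"),
      coverage = file.path(out_dir, "coverage.tsv"),
      vcf = stats::setNames(file.path(out_dir, paste0(acc_names, ".vcf")),
                            acc_names))
    Biostrings::writeXStringSet(ref$sequences, paths$fasta)
    write_gff3(ref$genes, paths$gff3)
    writeLines(sprintf("%s\t%d", config$layout$chromosomes$name,
                       as.integer(config$layout$chromosomes$length_bp)),
               paths$layout)
    write_coverage(coverage, paths$coverage)
    for (a in acc_names)
      write_vcf(callsets[[a]], paths$vcf[[a]], config$layout)
    write_truth(truth, file.path(out_dir, "truth"))
    out$paths <- paths
  }
  out
}

# per-gene true effect counts per accession, by full translation
gene_effect_truth <- function(callsets, genes, ref_seqs) {
  rows <- list()
  for (a in names(callsets)) {
    snps <- callsets[[a]]$snps
    for (gid in names(genes)) {
      g <- genes[[gid]]
      hit <- snps[snps$chrom == g$chrom & snps$pos >= g$gene_span[1] &
                    snps$pos <= g$gene_span[2], , drop = FALSE]
      eff <- if (nrow(hit)) vapply(seq_len(nrow(hit)), function(i)
        classify_by_full_translation(hit[i, ], g, ref_seqs), "") else character()
      rows[[length(rows) + 1]] <- data.frame(
        accession_id = a, gene_id = gid, snp_count = nrow(hit),
        ns_snp_count = sum(eff %in% c("nonsynonymous", "stop_gained", "stop_lost")),
        syn_snp_count = sum(eff == "synonymous"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the planted truth of a simulation
#'
#' One BED per accession (`truth_<accession>.bed`, labels preserved so that
#' [read_regions_bed()] round trips) and a TSV of true per-gene effect
#' counts.
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param dir output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  regions <- truth$regions
  accs <- if (is.null(regions)) character() else unique(regions$accession_id)
  for (a in accs) {
    r <- regions[regions$accession_id == a, , drop = FALSE]
    write_regions_bed(data.frame(chrom = r$chrom, start = r$start, end = r$end,
                                 label = r$label, score = r$multiplier),
                      file.path(dir, paste0("truth_", a, ".bed")))
  }
  eff <- truth$gene_effects
  con <- file(file.path(dir, "gene_effects.tsv"), "wb")
  writeLines(c("accession_id\tgene_id\tsnp_count\tns_snp_count\tsyn_snp_count",
               if (!is.null(eff) && nrow(eff))
                 sprintf("%s\t%s\t%d\t%d\t%d", eff$accession_id, eff$gene_id,
                         eff$snp_count, eff$ns_snp_count, eff$syn_snp_count)),
             con, sep = "\n")
  close(con)
  invisible(dir)
}
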