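# Domain types and file I/O. All internal coordinates are 1-based inclusive;
# BED files are the only place the 0-based half-open convention appears, and
# they are converted at the boundary.

#' Genome layout: chromosome names, lengths and optional centromeres
#'
#' The coordinate frame every other object in the package is validated
#' against. Chromosome order is the order given here and is preserved in all
#' sorted output.
#'
#' @param chromosomes data.frame with columns `name` (character, unique) and
#'   `length_bp` (positive integer), or a named numeric vector of lengths.
#' @param centromeres optional named numeric vector of centromere midpoint
#'   positions (1-based bp); names must be chromosome names and every midpoint
#'   must lie within its chromosome.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 5e6, chr2 = 3e6), centromeres = c(chr1 = 2.5e6))
#' @export
genome_layout <- function(chromosomes, centromeres = NULL) {
  if (is.numeric(chromosomes)) {
    stopifnot(!is.null(names(chromosomes)))
    chromosomes <- data.frame(name = names(chromosomes),
                              length_bp = unname(chromosomes))
  }
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length_bp <- as.numeric(chromosomes$length_bp)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names in layout")
  if (any(chromosomes$length_bp < 1) || anyNA(chromosomes$length_bp))
    stop("chromosome lengths must be positive")
  if (!is.null(centromeres)) {
    if (is.null(names(centromeres)) || !all(names(centromeres) %in% chromosomes$name))
      stop("centromere names must match layout chromosome names")
    len <- chromosomes$length_bp[match(names(centromeres), chromosomes$name)]
    if (any(centromeres < 1 | centromeres > len))
      stop("centromere midpoint outside its chromosome")
  }
  structure(list(chromosomes = chromosomes[, c("name", "length_bp")],
                 centromeres = centromeres),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %.2f Mb total\n",
              nrow(x$chromosomes), sum(x$chromosomes$length_bp) / 1e6))
  print(x$chromosomes, row.names = FALSE)
  if (!is.null(x$centromeres)) {
    cat("centromere midpoints:\n")
    print(x$centromeres)
  }
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  layout$chromosomes$length_bp[i]
}

#' Read chromosome lengths from a two-column TSV (name<TAB>length)
#'
#' @param path path to a tab-separated file without header.
#' @return A [genome_layout()].
#' @export
read_chrom_lengths <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, col.names = c("name", "length_bp"),
                           colClasses = c("character", "numeric"))
  genome_layout(tab)
}

#' Derive a genome layout from a FASTA reference
#'
#' @param fasta path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param centromeres optional named centromere midpoints, see [genome_layout()].
#' @export
layout_from_fasta <- function(fasta, centromeres = NULL) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_layout(stats::setNames(Biostrings::width(seqs), names(seqs)), centromeres)
}

#' Construct a per-accession SNP call set
#'
#' A call set holds biallelic single-base substitutions of one accession
#' relative to the reference, at most one per (chromosome, position), sorted
#' by layout chromosome order then position. Genotypes are not modelled: the
#' presence of a record means the accession carries a SNP at that position.
#'
#' @param accession_id character scalar.
#' @param snps data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single bases in A/C/G/T, `alt != ref`).
#' @param layout a [genome_layout()]; positions are validated against it.
#' @return Object of class `snp_callset`: list with `accession_id` and the
#'   sorted `snps` data.frame.
#' @export
snp_callset <- function(accession_id, snps, layout) {
  stopifnot(is.character(accession_id), length(accession_id) == 1)
  if (nrow(snps) == 0) {
    snps <- data.frame(chrom = character(), pos = numeric(),
                       ref = character(), alt = character())
  } else {
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snps)))
    snps <- data.frame(chrom = as.character(snps$chrom), pos = as.numeric(snps$pos),
                       ref = as.character(snps$ref), alt = as.character(snps$alt))
    bases <- c("A", "C", "G", "T")
    if (!all(snps$ref %in% bases) || !all(snps$alt %in% bases))
      stop("ref/alt must be single bases in A, C, G, T")
    if (any(snps$ref == snps$alt)) stop("alt allele equal to ref allele")
    len <- chrom_length(layout, snps$chrom)
    if (any(snps$pos < 1 | snps$pos > len))
      stop("SNP position outside chromosome bounds")
    key <- paste(snps$chrom, snps$pos)
    if (anyDuplicated(key)) stop("more than one record at the same (chrom, pos)")
    ord <- order(match(snps$chrom, layout$chromosomes$name), snps$pos)
    snps <- snps[ord, , drop = FALSE]
    rownames(snps) <- NULL
  }
  structure(list(accession_id = accession_id, snps = snps),
            class = "snp_callset")
}

#' @export
print.snp_callset <- function(x, ...) {
  cat(sprintf("snp_callset '%s': %d SNPs on %d chromosome(s)\n",
              x$accession_id, nrow(x$snps), length(unique(x$snps$chrom))))
  invisible(x)
}

#' Number of SNPs in a call set
#' @param x a `snp_callset`.
#' @export
n_snps <- function(x) nrow(x$snps)

#' Read SNPs from a VCF into a call set
#'
#' Keeps biallelic substitutions only. Multi-allelic sites are decomposed and
#' the first alternate allele kept (one position = one polymorphism). Indels,
#' MNPs, records on chromosomes absent from the layout, and duplicate
#' positions are dropped; the dropped counts are reported via `message()` and
#' attached as attribute `"dropped"` so that kept + dropped always equals the
#' number of input records.
#'
#' @param path VCF 4.x file (uncompressed text).
#' @param layout a [genome_layout()]; records beyond a chromosome's length are
#'   an error.
#' @param accession_id accession name; defaults to the file base name.
#' @return A [snp_callset()] with attributes `dropped` (named integer vector)
#'   and `n_input` (number of data lines read).
#' @export
read_vcf <- function(path, layout, accession_id = NULL) {
  if (is.null(accession_id))
    accession_id <- sub("\\.vcf$", "", basename(path))
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  dropped <- c(indel = 0L, mnp = 0L, unknown_chrom = 0L, duplicate = 0L)
  if (length(body_idx) == 0) {
    cs <- snp_callset(accession_id, data.frame(), layout)
    attr(cs, "dropped") <- dropped
    attr(cs, "n_input") <- 0L
    return(cs)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    bad <- body_idx[which(nf < 8)[1]]
    stop(sprintf("malformed VCF line %d in %s: fewer than 8 tab-separated fields",
                 bad, path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos)) {
    bad <- body_idx[which(is.na(pos))[1]]
    stop(sprintf("malformed VCF line %d in %s: POS is not a number", bad, path))
  }
  ref <- toupper(vapply(fields, `[[`, "", 4L))
  alt <- toupper(vapply(fields, `[[`, "", 5L))
  # decompose multi-allelic sites: first ALT allele only
  alt <- sub(",.*$", "", alt)

  known <- chrom %in% layout$chromosomes$name
  dropped["unknown_chrom"] <- sum(!known)
  is_snp <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
  # single-base records that are not simple substitutions (e.g. ALT ".", "N")
  # are counted with the indel/MNP classes by length
  dropped["indel"] <- sum(known & !is_snp & (nchar(ref) != nchar(alt)))
  dropped["mnp"] <- sum(known & !is_snp & (nchar(ref) == nchar(alt)))
  keep <- known & is_snp
  if (any(keep)) {
    over <- pos[keep] > chrom_length(layout, chrom[keep])
    if (any(over)) {
      bad <- body_idx[keep][which(over)[1]]
      stop(sprintf("VCF line %d in %s: position %d beyond chromosome end",
                   bad, path, as.integer(pos[keep][over][1])))
    }
  }
  key <- paste(chrom, pos)
  dup <- keep & duplicated(key)
  dropped["duplicate"] <- sum(dup)
  keep <- keep & !dup
  cs <- snp_callset(accession_id,
                    data.frame(chrom = chrom[keep], pos = pos[keep],
                               ref = ref[keep], alt = alt[keep]),
                    layout)
  if (sum(dropped) > 0)
    message(sprintf("read_vcf(%s): kept %d of %d records (dropped: %s)",
                    basename(path), sum(keep), length(body_idx),
                    paste(names(dropped), dropped, sep = "=", collapse = ", ")))
  attr(cs, "dropped") <- dropped
  attr(cs, "n_input") <- length(body_idx)
  cs
}

#' Write a call set as a minimal VCF 4.2 file
#'
#' Emits contig headers from the layout and one sorted data line per SNP;
#' round trips through [read_vcf()] exactly.
#'
#' @param callset a [snp_callset()].
#' @param path output path.
#' @param layout the [genome_layout()] used for contig headers and ordering.
#' @export
write_vcf <- function(callset, path, layout) {
  snps <- callset$snps
  ord <- order(match(snps$chrom, layout$chromosomes$name), snps$pos)
  snps <- snps[ord, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=desertscan"),
           sprintf("##contig=<ID=%s,length=%d>",
                   layout$chromosomes$name, as.integer(layout$chromosomes$length_bp)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
            snps$chrom, as.integer(snps$pos), snps$ref, snps$alt)
  } else character()
  con <- file(path, "wb")  # binary: byte-identical output across platforms
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Construct a protein-coding gene model
#'
#' @param gene_id character scalar.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param cds_segments two-column matrix or data.frame of 1-based inclusive
#'   (start, end) CDS segments; sorted by start, non-overlapping, and within
#'   `gene_span`.
#' @param gene_span length-2 vector (start, end) of the gene locus.
#' @return Object of class `gene_model`. If the summed CDS length is not a
#'   multiple of 3 the model is kept (it still counts as an annotated gene)
#'   but flagged `cds_incomplete`, which excludes it from effect
#'   classification.
#' @export
gene_model <- function(gene_id, chrom, strand, cds_segments, gene_span) {
  stopifnot(strand %in% c("+", "-"), length(gene_span) == 2)
  seg <- as.matrix(cds_segments)
  colnames(seg) <- c("start", "end")
  storage.mode(seg) <- "numeric"
  seg <- seg[order(seg[, 1]), , drop = FALSE]
  if (any(seg[, 2] < seg[, 1])) stop("CDS segment with end < start")
  if (nrow(seg) > 1 && any(seg[-1, 1] <= seg[-nrow(seg), 2]))
    stop("overlapping CDS segments in gene ", gene_id)
  if (seg[1, 1] < gene_span[1] || seg[nrow(seg), 2] > gene_span[2])
    stop("CDS segments outside gene span in gene ", gene_id)
  cds_len <- sum(seg[, 2] - seg[, 1] + 1)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds_segments = seg, gene_span = as.numeric(gene_span),
                 cds_length = cds_len,
                 cds_incomplete = (cds_len %% 3 != 0)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s: %s:%d-%d (%s), %d CDS segment(s), %d bp CDS%s\n",
              x$gene_id, x$chrom, x$gene_span[1], x$gene_span[2], x$strand,
              nrow(x$cds_segments), x$cds_length,
              if (x$cds_incomplete) " [CDS length not a multiple of 3]" else ""))
  invisible(x)
}

gene_span_length_kb <- function(gene) (gene$gene_span[2] - gene$gene_span[1] + 1) / 1000

#' Read gene models from a GFF3 file
#'
#' Expects gene/mRNA/CDS features with ID/Parent attributes. One model is
#' returned per gene; when a gene has several transcripts the one with the
#' longest summed CDS is kept. Genes whose CDS length is not a multiple of 3
#' are kept but flagged (see [gene_model()]).
#'
#' @param path GFF3 file.
#' @return Named list of [gene_model()] objects, in file order of the gene
#'   features.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_parent <- vapply(cds$Parent, function(p) p[[1]], "")
  mrna_parent <- vapply(mrnas$Parent, function(p) p[[1]], "")
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrnas[mrna_parent == gid, , drop = FALSE]
    parents <- if (nrow(tx)) tx$ID else gid  # CDS may hang off the gene directly
    best <- NULL
    for (p in parents) {
      seg <- cds[cds_parent == p, c("start", "end"), drop = FALSE]
      if (nrow(seg) == 0) next
      if (is.null(best) || sum(seg$end - seg$start + 1) > sum(best$end - best$start + 1))
        best <- seg
    }
    if (is.null(best)) next
    out[[gid]] <- gene_model(gid, as.character(genes$seqnames[i]),
                             as.character(genes$strand[i]), best,
                             c(genes$start[i], genes$end[i]))
  }
  out
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features with ID/Parent attributes so that
#' [read_gff3()] round trips to the same models.
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  if (length(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- lapply(genes, function(g) {
    ns <- nrow(g$cds_segments)
    w <- g$cds_segments[, 2] - g$cds_segments[, 1] + 1
    # phase: bases to skip before the first full codon, in reading order
    w_read <- if (g$strand == "-") rev(w) else w
    ph_read <- c(0, (3 - cumsum(w_read) %% 3) %% 3)[seq_len(ns)]
    phase <- if (g$strand == "-") rev(ph_read) else ph_read
    data.frame(
      seqnames = g$chrom,
      start = c(g$gene_span[1], g$gene_span[1], g$cds_segments[, 1]),
      end = c(g$gene_span[2], g$gene_span[2], g$cds_segments[, 2]),
      strand = g$strand,
      type = c("gene", "mRNA", rep("CDS", ns)),
      phase = c(NA_integer_, NA_integer_, as.integer(phase)),
      ID = c(g$gene_id, paste0(g$gene_id, ".1"), rep(NA_character_, ns)),
      Parent = c(NA_character_, g$gene_id, rep(paste0(g$gene_id, ".1"), ns)))
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$source <- "desertscan"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read labelled regions from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package's 1-based
#' inclusive convention on read (start + 1, end unchanged).
#'
#' @param path BED file (3 or more columns; column 4, when present, is kept
#'   as `label`).
#' @return data.frame with columns chrom, start, end, label (1-based
#'   inclusive).
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), label = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) stop("BED line with fewer than 3 columns in ", path)
  start0 <- as.numeric(vapply(fields, `[[`, "", 2L))
  end0 <- as.numeric(vapply(fields, `[[`, "", 3L))
  if (any(start0 >= end0)) stop("BED interval with start >= end in ", path)
  data.frame(chrom = vapply(fields, `[[`, "", 1L),
             start = start0 + 1, end = end0,
             label = vapply(fields, function(f) if (length(f) >= 4) f[[4]] else ".", ""))
}

#' Write labelled regions to a BED file (0-based half-open)
#'
#' @param regions data.frame with chrom, start, end (1-based inclusive) and
#'   optional label and score columns.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(regions)) {
    label <- if ("label" %in% names(regions)) regions$label else "."
    cols <- sprintf("%s\t%d\t%d\t%s", regions$chrom,
                    as.integer(regions$start - 1), as.integer(regions$end), label)
    if ("score" %in% names(regions))
      cols <- sprintf("%s\t%g", cols, regions$score)
    writeLines(cols, con, sep = "\n")
  }
  invisible(path)
}

#' Read a coverage track (TSV: chrom, start, end, mean_depth; 1-based inclusive)
#' @param path tab-separated file with a header line.
#' @return data.frame of class `coverage_track`.
#' @export
read_coverage <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "numeric",
                                                "numeric", "numeric"))
  names(tab) <- c("chrom", "start", "end", "mean_depth")
  if (any(tab$mean_depth < 0)) stop("negative depth in coverage track")
  class(tab) <- c("coverage_track", "data.frame")
  tab
}

#' Write a coverage track TSV
#' @param coverage data.frame with chrom, start, end, mean_depth.
#' @param path output path.
#' @export
write_coverage <- function(coverage, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("chrom\tstart\tend\tmean_depth",
               sprintf("%s\t%d\t%d\t%g", coverage$chrom,
                       as.integer(coverage$start), as.integer(coverage$end),
                       coverage$mean_depth)), con, sep = "\n")
  invisible(path)
}

#' Read a reference FASTA with names trimmed to the first token
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
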