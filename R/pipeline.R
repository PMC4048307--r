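# End-to-end orchestration: read inputs, scan, call deserts, delineate
# sweeps, report gene diversity, and write a self-describing output
# directory. Re-running with identical inputs and seed reproduces identical
# outputs (no timestamps in any artifact).

#' Assemble and validate a pipeline run configuration
#'
#' @param layout a [genome_layout()] or path to a lengths TSV.
#' @param vcfs named character vector: accession id -> VCF path.
#' @param out_dir output directory.
#' @param gff3,fasta,coverage,loci optional paths (gene models, reference
#'   sequence, coverage track, candidate-locus TSV) enabling the gene and
#'   sweep stages.
#' @param centromeres optional named vector of centromere midpoints (used
#'   when `layout` is a path).
#' @param window_bp scan window (default 100 kb).
#' @param desert_threshold,desert_min_windows,desert_max_gap
#'   [detect_deserts()] parameters.
#' @param sweep_flank_bp,sweep_frac_threshold,sweep_smooth_k
#'   [sweep_extent()] parameters.
#' @param min_depth,min_fraction,low_diversity_threshold [gene_report()]
#'   parameters.
#' @param reference_accession accession used to delineate desert/sweep
#'   intervals; defaults to the first VCF.
#' @param wild_accessions accessions defining the `low_diversity` gene flag.
#' @param region optional "chrom:start-end" string restricting the gene
#'   report.
#' @param seed seed echoed to the log (the analysis itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(layout, vcfs, out_dir,
                       gff3 = NULL, fasta = NULL, coverage = NULL, loci = NULL,
                       centromeres = NULL,
                       window_bp = 100000,
                       desert_threshold = 10, desert_min_windows = 4,
                       desert_max_gap = 1,
                       sweep_flank_bp = 1e6, sweep_frac_threshold = 0.5,
                       sweep_smooth_k = 51,
                       min_depth = 4, min_fraction = 0.8,
                       low_diversity_threshold = 1.0,
                       reference_accession = NULL, wild_accessions = NULL,
                       region = NULL, seed = 1) {
  if (is.character(layout)) {
    if (!file.exists(layout)) stop("layout file not found: ", layout)
    layout <- read_chrom_lengths(layout)
    if (!is.null(centromeres))
      layout <- genome_layout(layout$chromosomes, centromeres)
  }
  stopifnot(inherits(layout, "genome_layout"),
            is.character(vcfs), length(vcfs) >= 1, !is.null(names(vcfs)))
  for (p in c(vcfs, gff3, fasta, coverage, loci))
    if (!file.exists(p)) stop("input file not found: ", p)
  stopifnot(window_bp >= 1000, desert_threshold > 0,
            sweep_frac_threshold > 0, sweep_frac_threshold < 1,
            sweep_smooth_k %% 2 == 1,
            min_fraction >= 0, min_fraction <= 1)
  if (is.null(reference_accession)) reference_accession <- names(vcfs)[1]
  stopifnot(reference_accession %in% names(vcfs))
  structure(list(layout = layout, vcfs = vcfs, out_dir = out_dir,
                 gff3 = gff3, fasta = fasta, coverage = coverage, loci = loci,
                 window_bp = window_bp,
                 desert_threshold = desert_threshold,
                 desert_min_windows = desert_min_windows,
                 desert_max_gap = desert_max_gap,
                 sweep_flank_bp = sweep_flank_bp,
                 sweep_frac_threshold = sweep_frac_threshold,
                 sweep_smooth_k = sweep_smooth_k,
                 min_depth = min_depth, min_fraction = min_fraction,
                 low_diversity_threshold = low_diversity_threshold,
                 reference_accession = reference_accession,
                 wild_accessions = wild_accessions,
                 region = region, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `vcfs` is a named map of
#' accession id to path; relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  args <- list(layout = rel(y$layout),
               vcfs = stats::setNames(vapply(y$vcfs, rel, ""), names(y$vcfs)),
               out_dir = out_dir %||% y$out_dir %||% "desertscan_out",
               gff3 = rel(y$gff3), fasta = rel(y$fasta),
               coverage = rel(y$coverage), loci = rel(y$loci))
  if (!is.null(y$centromeres)) args$centromeres <- unlist(y$centromeres)
  for (k in c("window_bp", "desert_threshold", "desert_min_windows",
              "desert_max_gap", "sweep_flank_bp", "sweep_frac_threshold",
              "sweep_smooth_k", "min_depth", "min_fraction",
              "low_diversity_threshold", "reference_accession",
              "wild_accessions", "region", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("region must be 'chrom:start-end', got: ", region)
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

write_tsv <- function(df, path) {
  con <- file(path, "wb")
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Reads every input named in the configuration and writes to the output
#' directory: `windows.tsv` (all accessions' window scans), `deserts.bed`
#' and `deserts.tsv` (detected polymorphism deserts, BED score =
#' -log10(p) capped at 300), `sweeps.tsv` (per-locus sweep table, when loci
#' are given), `genes.tsv` and `gene_summary.tsv` (when gene models and a
#' reference are given), `summary.json` (per-accession totals and SNPs/kb,
#' desert intervals with per-accession densities and t-test p-values, the
#' sweep table), and `run.log` echoing every parameter and the
#' dropped-record accounting of each VCF.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every stage's in-memory result and
#'   `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("desertscan run", "parameters:")
  for (k in setdiff(names(config), c("layout", "vcfs")))
    log_lines <- c(log_lines, sprintf("  %s: %s", k,
                                      paste(unlist(config[[k]]), collapse = ", ")))
  layout <- config$layout

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  callsets <- stage("read_vcf", {
    out <- list()
    for (a in names(config$vcfs)) {
      cs <- suppressMessages(read_vcf(config$vcfs[[a]], layout, accession_id = a))
      d <- attr(cs, "dropped")
      log_lines <<- c(log_lines,
                      sprintf("vcf %s: kept %d of %d records (%s)", a, n_snps(cs),
                              attr(cs, "n_input"),
                              paste(names(d), d, sep = "=", collapse = ", ")))
      out[[a]] <- cs
    }
    out
  })

  windows <- stage("window_scan", {
    w <- do.call(rbind, lapply(callsets, scan_windows, layout = layout,
                               window_bp = config$window_bp))
    rownames(w) <- NULL
    write_tsv(w[, c("accession_id", "chrom", "start", "end", "snp_count",
                    "density", "partial")],
              file.path(config$out_dir, "windows.tsv"))
    w
  })

  deserts <- stage("desert_detection", {
    per <- list()
    for (a in names(callsets)) {
      wa <- windows[windows$accession_id == a, , drop = FALSE]
      for (ch in unique(wa$chrom)) {
        per[[length(per) + 1]] <- detect_deserts(
          wa[wa$chrom == ch, , drop = FALSE],
          threshold_per_100kb = config$desert_threshold,
          min_windows = config$desert_min_windows,
          max_gap_windows = config$desert_max_gap)
      }
    }
    d <- do.call(rbind, per)
    rownames(d) <- NULL
    write_tsv(d, file.path(config$out_dir, "deserts.tsv"))
    bed <- data.frame(chrom = d$chrom, start = d$start, end = d$end,
                      label = d$accession_id,
                      score = pmin(300, -log10(pmax(d$p_value, 1e-300))))
    bed$score[is.na(d$p_value)] <- 0
    write_regions_bed(bed, file.path(config$out_dir, "deserts.bed"))
    d
  })

  sweeps <- NULL
  if (!is.null(config$loci)) {
    sweeps <- stage("sweep_delineation", {
      loci <- read_loci(config$loci, layout)
      tab <- sweep_table(callsets, loci, layout,
                         reference_accession = config$reference_accession,
                         flank_bp = config$sweep_flank_bp,
                         frac_threshold = config$sweep_frac_threshold,
                         smooth_k = config$sweep_smooth_k)
      write_tsv(tab, file.path(config$out_dir, "sweeps.tsv"))
      tab
    })
  }

  genes_out <- NULL
  if (!is.null(config$gff3) && !is.null(config$fasta)) {
    genes_out <- stage("gene_diversity", {
      genes <- read_gff3(config$gff3)
      ref_seqs <- read_reference_fasta(config$fasta)
      cov <- if (!is.null(config$coverage)) read_coverage(config$coverage)
      region <- if (!is.null(config$region)) parse_region(config$region)
      rep <- gene_report(callsets, genes, ref_seqs, coverage = cov,
                         region = region,
                         wild_accessions = config$wild_accessions,
                         low_diversity_threshold = config$low_diversity_threshold,
                         min_depth = config$min_depth,
                         min_fraction = config$min_fraction)
      write_tsv(rep$genes, file.path(config$out_dir, "genes.tsv"))
      write_tsv(rep$summary, file.path(config$out_dir, "gene_summary.tsv"))
      log_lines <<- c(log_lines,
                      sprintf("genes: %d annotated, %d covered, %d uncovered",
                              length(genes),
                              length(genes) - length(rep$uncovered),
                              length(rep$uncovered)))
      rep
    })
  }

  summary <- stage("summary", {
    genome_kb <- sum(layout$chromosomes$length_bp) / 1000
    acc_summ <- lapply(callsets, function(cs) {
      per_chrom <- chrom_summary(cs, layout)
      list(total_snps = n_snps(cs),
           snps_per_kb = round_half_up(n_snps(cs) / genome_kb, 2),
           chromosomes = stats::setNames(
             lapply(seq_len(nrow(per_chrom)), function(i)
               list(total_snps = per_chrom$total_snps[i],
                    snps_per_kb = round_half_up(per_chrom$mean_density[i], 2))),
             per_chrom$chrom))
    })
    # densities of every accession over the reference accession's deserts
    ref_deserts <- deserts[deserts$accession_id == config$reference_accession, ,
                           drop = FALSE]
    desert_summ <- lapply(seq_len(nrow(ref_deserts)), function(i) {
      r <- ref_deserts[i, ]
      dens <- lapply(callsets, function(cs) {
        di <- density_in_interval(cs, layout, r$chrom, r$start, r$end)
        list(count = di$count,
             snps_per_kb = round_half_up(di$density, 3))
      })
      list(chrom = r$chrom, start = r$start, end = r$end,
           length_kb = r$length_kb, p_value = r$p_value,
           accessions = dens)
    })
    s <- list(accessions = acc_summ, deserts = desert_summ)
    if (!is.null(sweeps) && nrow(sweeps)) s$sweeps <- sweeps
    if (!is.null(genes_out) && nrow(genes_out$summary))
      s$gene_summary <- genes_out$summary
    jsonlite::write_json(s, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    s
  })

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(out_dir = config$out_dir, callsets = callsets,
                 windows = windows, deserts = deserts, sweeps = sweeps,
                 genes = genes_out, summary = summary))
}

#' Render a markdown report (and plots) from a pipeline output directory
#'
#' Writes `report.md` summarising the window scans, deserts and sweeps, and
#' — when ggplot2 is installed — one density-track PNG per chromosome with
#' desert shading. Without ggplot2 a tables-only report is written, with a
#' warning.
#'
#' @param out_dir directory produced by [run_all()].
#' @return path to `report.md`, invisibly.
#' @export
make_report <- function(out_dir) {
  windows <- utils::read.delim(file.path(out_dir, "windows.tsv"))
  deserts_path <- file.path(out_dir, "deserts.tsv")
  deserts <- if (file.exists(deserts_path)) utils::read.delim(deserts_path)
             else data.frame()
  md <- c("# SNP diversity scan report", "",
          sprintf("Accessions: %s",
                  paste(unique(windows$accession_id), collapse = ", ")), "")
  md <- c(md, "## Polymorphism deserts", "")
  if (nrow(deserts)) {
    md <- c(md, "accession | chrom | start | end | length_kb | SNPs/kb | p",
            "--- | --- | --- | --- | --- | --- | ---",
            sprintf("%s | %s | %d | %d | %g | %.3f | %.3g",
                    deserts$accession_id, deserts$chrom,
                    as.integer(deserts$start), as.integer(deserts$end),
                    deserts$length_kb, deserts$density, deserts$p_value))
  } else md <- c(md, "None detected.")
  sweeps_path <- file.path(out_dir, "sweeps.tsv")
  if (file.exists(sweeps_path)) {
    sw <- utils::read.delim(sweeps_path)
    md <- c(md, "", "## Selective sweeps", "")
    if (nrow(sw)) {
      md <- c(md, paste(names(sw), collapse = " | "),
              paste(rep("---", ncol(sw)), collapse = " | "),
              apply(sw, 1, paste, collapse = " | "))
    } else md <- c(md, "None detected.")
  }
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    for (ch in unique(windows$chrom)) {
      w <- windows[windows$chrom == ch, ]
      p <- ggplot2::ggplot(w, ggplot2::aes(x = (start + end) / 2e6,
                                           y = density,
                                           colour = accession_id)) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::labs(x = sprintf("%s position (Mb)", ch), y = "SNPs/kb",
                      colour = "accession") +
        ggplot2::theme_minimal()
      dch <- deserts[deserts$chrom == ch, , drop = FALSE]
      if (nrow(dch))
        p <- p + ggplot2::annotate("rect", xmin = dch$start / 1e6,
                                   xmax = dch$end / 1e6, ymin = -Inf,
                                   ymax = Inf, alpha = 0.15)
      fn <- file.path(out_dir, sprintf("density_%s.png", ch))
      ggplot2::ggsave(fn, p, width = 8, height = 3, dpi = 120)
      md <- c(md, "", sprintf("![%s](density_%s.png)", ch, ch))
    }
  } else {
    warning("ggplot2 not installed; writing tables-only report")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(md, path)
  invisible(path)
}
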