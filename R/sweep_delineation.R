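# Selective-sweep extent around candidate loci at 1-kb resolution: extract a
# flanking interval, smooth the per-window densities with a centred rolling
# mean, and take the maximal below-threshold run containing the locus.

#' Candidate locus table constructor
#'
#' @param name locus names (e.g. sh4, PROG1, wx).
#' @param chrom chromosome of each locus.
#' @param position 1-based midpoint of the gene.
#' @param layout a [genome_layout()] for validation.
#' @return data.frame with columns name, chrom, position.
#' @export
candidate_loci <- function(name, chrom, position, layout) {
  if (any(position < 1 | position > chrom_length(layout, chrom)))
    stop("locus position outside chromosome")
  data.frame(name = as.character(name), chrom = as.character(chrom),
             position = as.numeric(position))
}

#' Read candidate loci from a TSV (name, chrom, position)
#' @param path tab-separated file with header.
#' @param layout a [genome_layout()].
#' @export
read_loci <- function(path, layout) {
  tab <- utils::read.delim(path)
  candidate_loci(tab[[1]], tab[[2]], tab[[3]], layout)
}

#' Extract the SNPs and 1-kb windows flanking a locus
#'
#' Takes the interval `[position - flank_bp, position + flank_bp]` (truncated
#' at chromosome ends and flagged), the call set restricted to it, and 1-kb
#' tumbling windows tiling it with per-window SNP counts.
#'
#' @param callset a [snp_callset()].
#' @param locus one-row data.frame or list with name, chrom, position.
#' @param layout a [genome_layout()].
#' @param flank_bp flank half-width (default 1 Mb: a 2 Mb interval).
#' @param window_bp window width for the local scan (default 1 kb).
#' @return list with `snps` (data.frame), `windows` (with counts and
#'   density), `interval`, `truncated` (logical), `locus`.
#' @export
extract_flank <- function(callset, locus, layout, flank_bp = 1e6, window_bp = 1000) {
  len <- chrom_length(layout, locus$chrom)
  start <- locus$position - flank_bp
  end <- locus$position + flank_bp
  truncated <- start < 1 || end > len
  start <- max(1, start); end <- min(len, end)
  snps <- callset$snps[callset$snps$chrom == locus$chrom &
                         callset$snps$pos >= start & callset$snps$pos <= end, ,
                       drop = FALSE]
  rownames(snps) <- NULL
  starts <- seq(start, end, by = window_bp)
  ends <- pmin(starts + window_bp - 1, end)
  windows <- data.frame(chrom = locus$chrom, start = starts, end = ends,
                        length_bp = ends - starts + 1,
                        partial = (ends - starts + 1) < window_bp)
  windows <- count_snps_per_window(
    structure(list(accession_id = callset$accession_id, snps = snps),
              class = "snp_callset"),
    windows)
  list(snps = snps, windows = windows, interval = c(start, end),
       truncated = truncated, locus = locus,
       accession_id = callset$accession_id)
}

#' Delineate the sweep region around a locus
#'
#' Per-window densities are smoothed with a centred rolling mean of
#' `smooth_k` windows (shrinking at the interval edges). The sweep is the
#' maximal run of consecutive smoothed windows below
#' `frac_threshold * chrom_mean_density` that contains the locus window;
#' `detected = FALSE` when the locus window itself is not below threshold.
#' Length, count and density are computed on the raw (unsmoothed) windows of
#' the run. The default half-mean threshold places each boundary where the
#' smoothed profile crosses midway between the background rate and a deep
#' sweep floor, which estimates the true edge without systematic bias; see
#' the vignette.
#'
#' @param flank output of [extract_flank()], or a windows data.frame centred
#'   on the locus together with `locus`.
#' @param chrom_mean_density chromosome-wide mean SNPs/kb (> 0).
#' @param frac_threshold fraction of `chrom_mean_density` below which a
#'   smoothed window counts as swept (default 0.5).
#' @param smooth_k rolling-mean width in windows; must be odd (default 51).
#' @return one-row data.frame: locus, accession_id, chrom, start, end,
#'   length_kb, snp_count, density, detected.
#' @export
sweep_extent <- function(flank, chrom_mean_density, frac_threshold = 0.5,
                         smooth_k = 51) {
  if (smooth_k %% 2 == 0) stop("smooth_k must be odd")
  if (chrom_mean_density <= 0) stop("chrom_mean_density must be positive")
  windows <- flank$windows
  locus <- flank$locus
  acc <- if (!is.null(flank$accession_id)) flank$accession_id
         else windows$accession_id[1] %||% NA_character_
  sm <- zoo::rollapply(windows$density, width = smooth_k, FUN = mean,
                       align = "center", partial = TRUE)
  low <- sm < frac_threshold * chrom_mean_density
  locus_idx <- which(windows$start <= locus$position & windows$end >= locus$position)
  if (length(locus_idx) != 1) stop("locus position not inside the window set")
  base <- data.frame(locus = locus$name, accession_id = acc,
                     chrom = locus$chrom, start = NA_real_, end = NA_real_,
                     length_kb = NA_real_, snp_count = NA_integer_,
                     density = NA_real_, detected = FALSE)
  if (!low[locus_idx]) return(base)
  i0 <- locus_idx
  while (i0 > 1 && low[i0 - 1]) i0 <- i0 - 1
  i1 <- locus_idx
  while (i1 < length(low) && low[i1 + 1]) i1 <- i1 + 1
  run <- seq(i0, i1)
  count <- sum(windows$snp_count[run])
  len_kb <- sum(windows$length_bp[run]) / 1000
  data.frame(locus = locus$name, accession_id = acc, chrom = locus$chrom,
             start = windows$start[i0], end = windows$end[i1],
             length_kb = len_kb, snp_count = count,
             density = count / len_kb, detected = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep summary table across accessions
#'
#' Reproduces the layout of per-locus sweep tables: the sweep interval is
#' delineated on one designated reference-cultivated accession, then every
#' accession's SNP count and density are measured over that same fixed
#' interval. Loci with no detected sweep in the reference accession are
#' omitted.
#'
#' @param callsets named list of [snp_callset()] objects.
#' @param loci data.frame from [candidate_loci()].
#' @param layout a [genome_layout()].
#' @param reference_accession name (in `callsets`) of the accession on which
#'   sweep extent is measured; defaults to the first.
#' @param flank_bp,frac_threshold,smooth_k passed to [extract_flank()] and
#'   [sweep_extent()].
#' @param decimals rounding for the per-accession density columns (default 2,
#'   as usually printed).
#' @return data.frame with one row per detected locus: locus, chrom, start,
#'   end, length_kb, then `density_<accession>` and `count_<accession>`
#'   column pairs for every accession.
#' @export
sweep_table <- function(callsets, loci, layout,
                        reference_accession = names(callsets)[1],
                        flank_bp = 1e6, frac_threshold = 0.5, smooth_k = 51,
                        decimals = 2) {
  stopifnot(length(callsets) >= 1, nrow(loci) >= 1,
            reference_accession %in% names(callsets))
  ref <- callsets[[reference_accession]]
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    fl <- extract_flank(ref, locus, layout, flank_bp = flank_bp)
    cmd <- density_in_interval(ref, layout, locus$chrom, 1,
                               chrom_length(layout, locus$chrom))$density
    sw <- sweep_extent(fl, cmd, frac_threshold = frac_threshold,
                       smooth_k = smooth_k)
    if (!sw$detected) next
    row <- data.frame(locus = locus$name, chrom = locus$chrom,
                      start = sw$start, end = sw$end, length_kb = sw$length_kb)
    for (acc in names(callsets)) {
      di <- density_in_interval(callsets[[acc]], layout, locus$chrom,
                                sw$start, sw$end)
      row[[paste0("density_", acc)]] <- region_density(di$count, sw$length_kb,
                                                       decimals)
      row[[paste0("count_", acc)]] <- di$count
    }
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0)
    return(data.frame(locus = character(), chrom = character(),
                      start = numeric(), end = numeric(), length_kb = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
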