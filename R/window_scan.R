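# Windowed SNP counting and the density/ratio arithmetic used throughout.
# Windows are non-overlapping ("tumbling"): [1, w], [w+1, 2w], ...; the final
# partial window keeps its true length and is flagged, so that totals are
# conserved while equal-support statistics can exclude it.

#' Tile a chromosome into non-overlapping windows
#'
#' @param layout a [genome_layout()].
#' @param chrom chromosome name.
#' @param window_bp window width in bp (default 100 kb; must be >= 1000).
#' @param step_bp step between window starts; defaults to `window_bp`
#'   (tumbling windows). A smaller step gives overlapping sliding windows;
#'   note count conservation only holds for the tumbling case.
#' @return data.frame with columns chrom, start, end, length_bp, partial
#'   (TRUE for a terminal window shorter than `window_bp`).
#' @export
tile_windows <- function(layout, chrom, window_bp = 100000, step_bp = window_bp) {
  stopifnot(window_bp >= 1000, step_bp >= 1)
  len <- chrom_length(layout, chrom)
  starts <- seq(1, len, by = step_bp)
  # drop sliding windows that would start past the end with nothing left
  ends <- pmin(starts + window_bp - 1, len)
  keep <- starts <= len
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(chrom = chrom, start = starts, end = ends,
             length_bp = ends - starts + 1,
             partial = (ends - starts + 1) < window_bp)
}

#' Count SNPs per window
#'
#' Each SNP is assigned to the window whose interval contains its position
#' (with tumbling windows, exactly one), so per-chromosome window counts sum
#' to the call set size on that chromosome. Density is SNPs per kb of the
#' window's true length.
#'
#' @param callset a [snp_callset()].
#' @param windows output of [tile_windows()] (one chromosome).
#' @return `windows` with `snp_count` and `density` columns added.
#' @export
count_snps_per_window <- function(callset, windows) {
  stopifnot(length(unique(windows$chrom)) <= 1)
  pos <- callset$snps$pos[callset$snps$chrom == windows$chrom[1]]
  w <- if (nrow(windows)) windows$length_bp[1] else 0
  tumbling <- nrow(windows) > 0 &&
    (nrow(windows) == 1 || all(diff(windows$start) == w))
  if (tumbling) {
    # regular grid: direct index arithmetic
    idx <- ceiling((pos - windows$start[1] + 1) / w)
    counts <- tabulate(idx[idx >= 1 & idx <= nrow(windows)], nbins = nrow(windows))
    # positions past the last window's true end don't belong to it
    if (any(idx == nrow(windows)))
      counts[nrow(windows)] <- sum(pos >= windows$start[nrow(windows)] &
                                     pos <= windows$end[nrow(windows)])
  } else {
    counts <- vapply(seq_len(nrow(windows)), function(i)
      sum(pos >= windows$start[i] & pos <= windows$end[i]), 0L)
  }
  windows$snp_count <- as.integer(counts)
  windows$density <- windows$snp_count / (windows$length_bp / 1000)
  windows
}

#' Scan all chromosomes of a call set
#'
#' Convenience wrapper: [tile_windows()] + [count_snps_per_window()] for every
#' chromosome in the layout, with the accession id attached.
#'
#' @inheritParams count_snps_per_window
#' @inheritParams tile_windows
#' @return data.frame of windows with counts for the whole genome.
#' @export
scan_windows <- function(callset, layout, window_bp = 100000) {
  res <- lapply(layout$chromosomes$name, function(ch)
    count_snps_per_window(callset, tile_windows(layout, ch, window_bp)))
  out <- do.call(rbind, res)
  out$accession_id <- callset$accession_id
  out
}

# round half away from zero to `decimals` places (base round() is banker's)
round_half_up <- function(x, decimals = 0) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' SNP density of a region, rounded as reported
#'
#' `snp_count / length_kb`, rounded half-up to `decimals` places — the
#' arithmetic behind per-region "SNPs per kb" table entries.
#'
#' @param snp_count non-negative SNP count.
#' @param length_kb region length in kb (> 0).
#' @param decimals decimal places to round to (default 2).
#' @examples
#' region_density(884, 357)       # 2.48
#' region_density(244, 4585, 3)   # 0.053
#' @export
region_density <- function(snp_count, length_kb, decimals = 2) {
  if (any(length_kb <= 0)) stop("length_kb must be positive")
  round_half_up(snp_count / length_kb, decimals)
}

#' SNP count and density in a genomic interval
#'
#' @param callset a [snp_callset()].
#' @param layout a [genome_layout()].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval bounds within the chromosome.
#' @return list with `count` and `density` (SNPs/kb, unrounded).
#' @export
density_in_interval <- function(callset, layout, chrom, start, end) {
  len <- chrom_length(layout, chrom)
  if (start > end || start < 1 || end > len)
    stop(sprintf("interval %d-%d outside chromosome %s (1-%d)",
                 start, end, chrom, as.integer(len)))
  pos <- callset$snps$pos[callset$snps$chrom == chrom]
  count <- sum(pos >= start & pos <= end)
  list(count = count, density = count / ((end - start + 1) / 1000))
}

#' Per-chromosome SNP summary
#'
#' @inheritParams density_in_interval
#' @return data.frame with chrom, total_snps, length_kb and mean_density
#'   (SNPs per kb over the full chromosome length).
#' @export
chrom_summary <- function(callset, layout) {
  chs <- layout$chromosomes
  counts <- vapply(chs$name, function(ch)
    sum(callset$snps$chrom == ch), 0L)
  data.frame(chrom = chs$name, total_snps = as.integer(counts),
             length_kb = chs$length_bp / 1000,
             mean_density = counts / (chs$length_bp / 1000),
             row.names = NULL)
}

#' Fold ratio of two SNP totals
#' @param a_total,b_total SNP totals; `b_total > 0`.
#' @export
fold_ratio <- function(a_total, b_total) {
  if (any(b_total <= 0)) stop("denominator total must be positive")
  a_total / b_total
}

#' Percent reduction of a region's density relative to its chromosome
#'
#' `100 * (1 - region_density / chrom_density)`: how much lower (percent) the
#' region's SNP rate is than the chromosome-wide mean.
#'
#' @param region_density region SNPs/kb.
#' @param chrom_density chromosome-wide SNPs/kb (> 0).
#' @export
percent_reduction <- function(region_density, chrom_density) {
  if (any(chrom_density <= 0)) stop("chrom_density must be positive")
  100 * (1 - region_density / chrom_density)
}
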