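# Polymorphism-desert calling from window scans. A desert is a maximal run of
# consecutive low-count windows (count below a per-100-kb threshold, rescaled
# to each window's true length), optionally bridging short gaps, long enough
# to rule out single-window noise.

#' Detect polymorphism deserts in a window scan
#'
#' A window is "low" when its SNP count is below
#' `threshold_per_100kb * length_bp / 1e5` (i.e. below the threshold rate of
#' SNPs per 100 kb, pro-rated for partial windows). Runs of low windows
#' separated by at most `max_gap_windows` consecutive non-low windows are
#' merged; a run is reported when it contains at least `min_windows` low
#' windows. The reported region spans the first to the last low window of the
#' run, with aggregate count and density and a Welch t-test of the region's
#' per-window density against the remainder of the chromosome (NA when either
#' side has fewer than two full windows).
#'
#' The defaults — a 10 SNPs/100 kb cut-off, a 4-window (400 kb) length floor
#' and a 1-window bridged gap — are analysis choices, not reconstructions of
#' any published delimitation rule; see the package vignette for the
#' rationale.
#'
#' @param windows one chromosome's windows with counts, from
#'   [count_snps_per_window()] or one chromosome of [scan_windows()].
#' @param threshold_per_100kb low-window cut-off in SNPs per 100 kb
#'   (default 10: "fewer than 10 SNPs per 100 kb").
#' @param min_windows minimum number of low windows in a reported run.
#' @param max_gap_windows maximum number of consecutive non-low windows
#'   bridged inside a run.
#' @return data.frame (possibly 0-row) with columns accession_id, chrom,
#'   start, end, n_windows, n_low_windows, snp_count, length_kb, density,
#'   p_value.
#' @export
detect_deserts <- function(windows, threshold_per_100kb = 10,
                           min_windows = 4, max_gap_windows = 1) {
  stopifnot(length(unique(windows$chrom)) == 1)
  windows <- windows[order(windows$start), , drop = FALSE]
  thr <- threshold_per_100kb * windows$length_bp / 1e5
  low <- windows$snp_count < thr
  empty <- data.frame(accession_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_windows = integer(), n_low_windows = integer(),
                      snp_count = integer(), length_kb = numeric(),
                      density = numeric(), p_value = numeric())
  if (!any(low)) return(empty)
  acc <- if ("accession_id" %in% names(windows)) windows$accession_id[1] else NA_character_
  li <- which(low)
  # split low-window indices where the gap exceeds max_gap_windows
  grp <- cumsum(c(1, diff(li) > max_gap_windows + 1))
  out <- lapply(split(li, grp), function(ix) {
    if (length(ix) < min_windows) return(NULL)
    span <- seq(min(ix), max(ix))
    count <- sum(windows$snp_count[span])
    len_kb <- sum(windows$length_bp[span]) / 1000
    reg <- data.frame(accession_id = acc, chrom = windows$chrom[1],
                      start = windows$start[min(ix)], end = windows$end[max(ix)],
                      n_windows = length(span), n_low_windows = length(ix),
                      snp_count = count, length_kb = len_kb,
                      density = count / len_kb, p_value = NA_real_)
    tt <- tryCatch(desert_vs_rest_test(windows, reg), error = function(e) NULL)
    if (!is.null(tt)) reg$p_value <- tt$p
    reg
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Welch t-test of window densities inside a region vs. the chromosome remainder
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on per-window SNP
#' densities, comparing full windows inside the region with full windows on
#' the rest of the same chromosome. Partial terminal windows are excluded
#' from both samples (unequal support). The degenerate all-equal case returns
#' t = 0, p = 1.
#'
#' @param windows one chromosome's windows with counts.
#' @param region list or one-row data.frame with `start` and `end` (window
#'   boundaries, 1-based inclusive).
#' @return list with `t`, `p`, `mean_in`, `mean_out`, `n_in`, `n_out`.
#' @export
desert_vs_rest_test <- function(windows, region) {
  full <- windows[!windows$partial, , drop = FALSE]
  inside <- full$start >= region$start[1] & full$end <= region$end[1]
  d_in <- full$density[inside]
  d_out <- full$density[!inside]
  if (length(d_in) < 2 || length(d_out) < 2)
    stop("desert_vs_rest_test: need at least 2 full windows on each side")
  if (stats::sd(d_in) == 0 && stats::sd(d_out) == 0) {
    eq <- mean(d_in) == mean(d_out)
    return(list(t = if (eq) 0 else sign(mean(d_in) - mean(d_out)) * Inf,
                p = if (eq) 1 else 0,
                mean_in = mean(d_in), mean_out = mean(d_out),
                n_in = length(d_in), n_out = length(d_out)))
  }
  tt <- stats::t.test(d_in, d_out, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_in = mean(d_in), mean_out = mean(d_out),
       n_in = length(d_in), n_out = length(d_out))
}

#' SNP density around a centromere vs. the whole chromosome
#'
#' Density within `[midpoint - flank_bp, midpoint + flank_bp]` (truncated at
#' chromosome ends, with a warning) against the chromosome-wide mean density,
#' and their ratio — used to ask whether a low-diversity region is explained
#' by centromeric recombination suppression alone.
#'
#' @param callset a [snp_callset()].
#' @param layout a [genome_layout()] whose `centromeres` include `chrom`.
#' @param chrom chromosome name.
#' @param flank_bp half-width of the centromeric interval (default 1 Mb, i.e.
#'   2 Mb centred on the centromere).
#' @return list with `centromere_density`, `chrom_density`, `ratio`,
#'   `interval` (start, end) and `count`.
#' @export
centromere_context <- function(callset, layout, chrom, flank_bp = 1e6) {
  if (is.null(layout$centromeres) || !(chrom %in% names(layout$centromeres)))
    stop("no centromere coordinate in layout for chromosome ", chrom)
  mid <- layout$centromeres[[chrom]]
  len <- chrom_length(layout, chrom)
  start <- mid - flank_bp
  end <- mid + flank_bp
  if (start < 1 || end > len) {
    warning(sprintf("centromere flank truncated to chromosome %s bounds", chrom))
    start <- max(1, start); end <- min(len, end)
  }
  cen <- density_in_interval(callset, layout, chrom, start, end)
  whole <- density_in_interval(callset, layout, chrom, 1, len)
  list(centromere_density = cen$density, chrom_density = whole$density,
       ratio = if (whole$density > 0) cen$density / whole$density else NA_real_,
       interval = c(start, end), count = cen$count)
}
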