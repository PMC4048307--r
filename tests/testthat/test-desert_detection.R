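windows_from_counts <- function(counts, window_bp = 1e5, chrom = "chr1") {
  n <- length(counts)
  data.frame(chrom = chrom, start = seq(1, by = window_bp, length.out = n),
             end = seq(window_bp, by = window_bp, length.out = n),
             length_bp = window_bp, partial = FALSE,
             snp_count = as.integer(counts),
             density = counts / (window_bp / 1000))
}

test_that("desert calls are maximal runs of low windows", {
  w <- windows_from_counts(c(12, 9, 3, 8, 15))
  d <- detect_deserts(w, min_windows = 3, max_gap_windows = 0)
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 100001)
  expect_equal(d$end, 400000)
  expect_equal(d$snp_count, 20L)
  expect_equal(d$n_windows, 3L)

  expect_equal(nrow(detect_deserts(windows_from_counts(c(15, 12, 10, 40)))), 0)

  # short runs below min_windows are dropped
  expect_equal(nrow(detect_deserts(windows_from_counts(c(50, 2, 50, 50, 50)),
                                   min_windows = 2)), 0)
})

test_that("gap bridging merges runs but never swallows long high stretches", {
  counts <- c(50, 2, 3, 30, 2, 4, 50, 50)
  d1 <- detect_deserts(windows_from_counts(counts), min_windows = 4,
                       max_gap_windows = 1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$start, 100001)
  expect_equal(d1$end, 600000)
  expect_equal(d1$n_low_windows, 4L)

  d0 <- detect_deserts(windows_from_counts(counts), min_windows = 2,
                       max_gap_windows = 0)
  expect_equal(nrow(d0), 2)
})

test_that("detection is invariant to window ordering and repeated calls", {
  set.seed(1)
  counts <- c(rpois(10, 300), rpois(6, 2), rpois(10, 300))
  w <- windows_from_counts(counts)
  d <- detect_deserts(w)
  d_shuf <- detect_deserts(w[sample(nrow(w)), ])
  expect_equal(d, d_shuf)
  expect_equal(detect_deserts(w), d)
  expect_equal(d$start, 1000001)
  expect_equal(d$end, 1600000)
})

test_that("threshold rescaling makes 50-kb and 100-kb scans agree on exact truth", {
  # noiseless desert: uniform SNPs outside a multiplier-0 interval
  lay <- genome_layout(c(chr1 = 3e6))
  pos <- seq(1, 3e6, by = 250)                    # 4 SNPs/kb everywhere
  desert <- pos >= 1200001 & pos <= 1900000       # 700-kb hole
  cs <- make_callset(lay, "chr1", pos[!desert])
  d100 <- detect_deserts(count_snps_per_window(cs, tile_windows(lay, "chr1", 1e5)))
  d50 <- detect_deserts(count_snps_per_window(cs, tile_windows(lay, "chr1", 5e4)),
                        min_windows = 8)
  expect_equal(nrow(d100), 1)
  expect_equal(nrow(d50), 1)
  expect_lte(abs(d50$start - d100$start), 1e5)
  expect_lte(abs(d50$end - d100$end), 1e5)
  expect_equal(d100$start, 1200001)
  expect_equal(d100$end, 1900000)
})

test_that("Welch test matches the textbook formula and degenerate cases", {
  w <- windows_from_counts(c(120, 90, 100, 480, 510, 530, 470))
  region <- list(start = 1, end = 300000)
  res <- desert_vs_rest_test(w, region)
  oracle <- welch_oracle(c(1.2, 0.9, 1.0), c(4.8, 5.1, 5.3, 4.7))
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$mean_in, mean(c(1.2, 0.9, 1.0)))
  expect_equal(res$mean_out, mean(c(4.8, 5.1, 5.3, 4.7)))

  # constant-but-different densities: Welch is undefined (0/0); the
  # implementation reports an infinite statistic at p = 0
  zv <- desert_vs_rest_test(windows_from_counts(c(100, 100, 500, 500, 500)),
                            list(start = 1, end = 200000))
  expect_equal(zv$t, -Inf)
  expect_equal(zv$p, 0)

  flat <- windows_from_counts(rep(200, 8))
  res2 <- desert_vs_rest_test(flat, list(start = 1, end = 400000))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  expect_error(desert_vs_rest_test(windows_from_counts(c(1, 2, 3)),
                                   list(start = 1, end = 100000)),
               "at least 2 full windows")
})

test_that("partial terminal windows are excluded from the test sample", {
  w <- windows_from_counts(c(10, 10, 500, 500, 500, 500))
  w$partial[6] <- TRUE
  w$length_bp[6] <- 5e4
  res <- desert_vs_rest_test(w, list(start = 1, end = 200000))
  expect_equal(res$n_out, 3)
})

test_that("centromere density ratio recovers planted centromeric suppression", {
  lay <- genome_layout(c(chr1 = 3e6), centromeres = c(chr1 = 1.5e6))
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 750000),
                                                 collapse = "")))
  # uniform chromosome: ratio ~ 1
  ratios <- vapply(1:20, function(s) {
    cs <- simulate_snp_set(diversity_profile(5), lay, ref, seed = 400 + s)
    centromere_context(cs, lay, "chr1")$ratio
  }, 0)
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se + 0.02)

  # planted 0.5 suppression within the 2-Mb centromeric interval
  prof <- diversity_profile(5, data.frame(chrom = "chr1", start = 500001,
                                          end = 2500000, multiplier = 0.5,
                                          label = "centromere"))
  ratios2 <- vapply(1:20, function(s) {
    cs <- simulate_snp_set(prof, lay, ref, seed = 600 + s)
    centromere_context(cs, lay, "chr1")$ratio
  }, 0)
  # whole-chromosome mean is diluted by the suppressed third:
  # expected ratio = 0.5 / ((1 + 2 * 0.5) / 3) = 0.75
  se2 <- stats::sd(ratios2) / sqrt(length(ratios2))
  expect_lt(abs(mean(ratios2) - 0.75), 3 * se2 + 0.02)
})

test_that("centromere flank truncates at chromosome ends with a warning", {
  lay <- genome_layout(c(chr1 = 1.5e6), centromeres = c(chr1 = 3e5))
  cs <- make_callset(lay, "chr1", seq(1, 1.5e6, by = 1000))
  expect_warning(res <- centromere_context(cs, lay, "chr1"), "truncated")
  expect_equal(res$interval, c(1, 1.3e6))
  expect_error(centromere_context(cs, genome_layout(c(chr1 = 1.5e6)), "chr1"),
               "no centromere")
})

test_that("planted desert is recovered and significant on the default scenario", {
  lay <- genome_layout(c(chr1 = 5e6))
  prof <- diversity_profile(2.5, data.frame(chrom = "chr1", start = 2200001,
                                            end = 2700000, multiplier = 0.02,
                                            label = "desert"))
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 1250000),
                                                 collapse = "")))
  cs <- simulate_snp_set(prof, lay, ref, seed = 12)
  d <- detect_deserts(count_snps_per_window(cs, tile_windows(lay, "chr1")))
  expect_equal(nrow(d), 1)
  expect_lte(abs(d$start - 2200001), 1e5)
  expect_lte(abs(d$end - 2700000), 1e5)
  expect_lt(d$p_value, 0.01)
})
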