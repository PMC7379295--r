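test_that("segment borders follow the midpoint and chromosome-tip rules", {
  # no donor allele anywhere -> no segments
  expect_equal(nrow(call_segments(rep("A", 5), c(1, 2, 3, 4, 5) * 1e6, 2e7)), 0L)

  # donor marker at 10 Mb, next recurrent at 12 Mb: border half-way
  pos <- c(8e6, 10e6, 12e6)
  seg <- call_segments(c("A", "B", "A"), pos, 2e7)
  expect_equal(seg$start_bp, 9e6)
  expect_equal(seg$end_bp, 11e6)
  expect_equal(seg$zygosity, "homozygous")

  # run reaching the first/last informative marker extends to the tips
  seg <- call_segments(c("B", "A", "B"), pos, 2e7)
  expect_equal(seg$start_bp, c(1L, 11e6))
  expect_equal(seg$end_bp, c(9e6, 2e7))

  # missing calls are transparent: they neither break nor extend a run
  seg <- call_segments(c("A", "U", "B", "U", "A"), c(1:5) * 1e6, 1e7)
  expect_equal(seg$start_bp, floor((1e6 + 3e6) / 2))
  expect_equal(seg$end_bp, floor((3e6 + 5e6) / 2))
  expect_equal(seg$n_markers, 1L)

  # a leading U does not block the tip rule
  seg <- call_segments(c("U", "B", "A"), pos, 2e7)
  expect_equal(seg$start_bp, 1L)

  # zygosity classification
  expect_equal(call_segments(c("H", "H", "A"), pos, 2e7)$zygosity, "heterozygous")
  expect_equal(call_segments(c("B", "H", "A"), pos, 2e7)$zygosity, "mixed")

  # all-missing chromosome warns and returns nothing
  expect_warning(out <- call_segments(rep("U", 3), pos, 2e7), "zero non-missing")
  expect_equal(nrow(out), 0L)
})

test_that("segment calling matches the brute-force oracle on random vectors", {
  set.seed(42)
  pos <- sort(sample(1e3:1e6, 12))
  chrom_len <- 1.2e6
  for (i in 1:400) {
    calls <- sample(c("A", "B", "H", "U"), 12, replace = TRUE)
    got <- suppressWarnings(call_segments(calls, pos, chrom_len))
    want <- suppressWarnings(oracle_segments(calls, pos, chrom_len))
    expect_equal(as.data.frame(got), want,
                 info = paste(calls, collapse = ""))
  }
})

test_that("segments stay in bounds, disjoint, and grow monotonically", {
  set.seed(7)
  pos <- sort(sample(1e3:1e6, 10))
  chrom_len <- 1.1e6
  for (i in 1:200) {
    calls <- sample(c("A", "B", "H", "U"), 10, replace = TRUE)
    seg <- suppressWarnings(call_segments(calls, pos, chrom_len))
    if (!nrow(seg)) next
    expect_true(all(seg$start_bp >= 1 & seg$end_bp <= chrom_len))
    expect_true(all(seg$start_bp <= seg$end_bp))
    if (nrow(seg) > 1) expect_true(all(seg$start_bp[-1] > seg$end_bp[-nrow(seg)]))
    # flipping any interior A to B never shrinks the total donor length
    a_idx <- which(calls == "A")
    if (length(a_idx)) {
      j <- sample(a_idx, 1)
      calls2 <- calls; calls2[j] <- "B"
      seg2 <- call_segments(calls2, pos, chrom_len)
      expect_gte(sum(seg2$end_bp - seg2$start_bp + 1),
                 sum(seg$end_bp - seg$start_bp + 1))
    }
  }
})

test_that("population summaries use per-line sums and union coverage", {
  cl <- tibble::tibble(chrom = "c1", length_bp = 100e6L)
  seg1 <- tibble::tibble(line_id = "L1", chrom = "c1",
                         start_bp = 1e6L, end_bp = as.integer(6e6 - 1),
                         zygosity = "homozygous", n_markers = 3L)
  s <- summarize_population(seg1, 1, cl)
  expect_equal(s$mean_sum_length_bp, 5e6)
  expect_equal(s$genome_coverage_fraction, 0.05)

  # an identical segment in a second line is counted once in coverage
  seg2 <- dplyr::mutate(seg1, line_id = "L2")
  s2 <- summarize_population(dplyr::bind_rows(seg1, seg2), 3, cl)
  expect_equal(s2$genome_coverage_fraction, 0.05)
  expect_equal(s2$n_lines_with_segment, 2L)
  expect_equal(s2$n_lines_without, 1L)
  expect_equal(s2$mean_segments_per_line, 1)
  expect_lte(s2$median_sum_length_bp, max(s2$mean_sum_length_bp, 5e6))
})

test_that("whole-population calling agrees with per-line calls", {
  map <- toy_map(c(2e6, 4e6, 6e6, 8e6))
  cl <- tibble::tibble(chrom = "c1", length_bp = 10e6L)
  geno <- toy_geno(map,
                   L1 = c("A", "B", "B", "A"),
                   L2 = c("A", "A", "A", "A"),
                   L3 = c("H", "A", "U", "B"))
  seg <- call_introgressions(geno, map, cl)
  expect_equal(unique(seg$line_id), c("L1", "L3"))
  l1 <- seg[seg$line_id == "L1", ]
  expect_equal(l1$start_bp, 3e6)
  expect_equal(l1$end_bp, 7e6)
  expect_equal(l1$n_markers, 2L)
  l3 <- seg[seg$line_id == "L3", ]
  expect_equal(l3$zygosity, c("heterozygous", "homozygous"))
  # second run: B at 8 Mb, nearest informative A at 4 Mb (U is skipped)
  expect_equal(l3$start_bp, c(1L, 6e6))
  expect_equal(l3$end_bp, c(3e6, 10e6))
})
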