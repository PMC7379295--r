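test_that("gamete formation honours degenerate cases", {
  h_donor <- list(ends = 0, alleles = 1L)
  h_rec <- list(ends = 0, alleles = 0L)
  set.seed(1)
  # a 0-cM chromosome transmits an intact parental haplotype
  g <- simulate_gamete(h_donor, h_rec, 0)
  expect_true(identical(g, h_donor) || identical(g, h_rec))
  # identical haplotypes come through unchanged regardless of crossovers
  h <- list(ends = c(30, 100), alleles = c(1L, 0L))
  expect_identical(simulate_gamete(h, h, 100), h)
})

test_that("crossover counts are Poisson with mean length in Morgans", {
  set.seed(20)
  h1 <- list(ends = 100, alleles = 1L)
  h2 <- list(ends = 100, alleles = 0L)
  n <- 10000
  # with fully distinct parental haplotypes every crossover is a
  # visible junction, so junctions count crossovers exactly
  k <- vapply(seq_len(n), function(i) {
    length(simulate_gamete(h1, h2, 100)$ends) - 1L
  }, integer(1))
  se <- sd(k) / sqrt(n)
  expect_lt(abs(mean(k) - 1), 3 * se)
  # gametes are valid haplotypes: ends increasing, terminating at 100
  g <- simulate_gamete(h1, h2, 100)
  expect_equal(g$ends[length(g$ends)], 100)
  expect_true(!is.unsorted(g$ends, strictly = TRUE))
  expect_equal(length(g$ends), length(g$alleles))
})

test_that("simulated populations are reproducible and truth-consistent", {
  cfg <- sim_config(n_lines = 12, n_chrom = 3, markers_per_chrom = 40, seed = 77)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth, s2$truth)

  # marker calls must agree with the truth segments they were read from
  st <- s1$truth
  for (i in seq_len(nrow(s1$marker_map))) {
    mk <- s1$marker_map[i, ]
    cover <- st[st$chrom == mk$chrom & st$start_bp <= mk$pos_bp &
                  st$end_bp >= mk$pos_bp, ]
    for (ln in s1$genotypes$line_id) {
      call <- s1$genotypes[[mk$marker_id]][s1$genotypes$line_id == ln]
      z <- cover$zygosity[cover$line_id == ln]
      want <- if (!length(z)) "A" else if (z == "homozygous") "B" else "H"
      expect_equal(call, want)
    }
  }
})

test_that("the caller recovers simulated segments within marker resolution", {
  cfg <- sim_config(n_lines = 20, n_chrom = 2, markers_per_chrom = 120, seed = 5)
  sim <- simulate_population(cfg)
  seg <- call_introgressions(sim$genotypes, sim$marker_map, sim$chrom_lengths)
  spacing <- sim$chrom_lengths$length_bp[1] / (cfg$markers_per_chrom + 1)
  truth <- sim$truth[(sim$truth$end_bp - sim$truth$start_bp) > 2 * spacing, ]
  for (k in seq_len(nrow(truth))) {
    tr <- truth[k, ]
    hit <- seg[seg$line_id == tr$line_id & seg$chrom == tr$chrom &
                 seg$start_bp <= tr$end_bp & seg$end_bp >= tr$start_bp, ]
    expect_gte(nrow(hit), 1)
    # borders within half the local marker spacing (+rounding slack)
    expect_lt(min(abs(hit$start_bp - tr$start_bp)), spacing / 2 + 2)
    expect_lt(min(abs(hit$end_bp - tr$end_bp)), spacing / 2 + 2)
  }
})

test_that("backcrossing dilutes donor content as expected", {
  # donor allele fraction after three backcrosses (before selfing)
  sim <- simulate_population(sim_config(n_lines = 250, n_chrom = 4,
                                        markers_per_chrom = 10,
                                        n_selfings = 0, seed = 31))
  fr <- truth_genome_fractions(sim)
  se <- sd(fr$donor_fraction) / sqrt(nrow(fr))
  expect_lt(abs(mean(fr$donor_fraction) - 1 / 16), 3 * se)
  # at this stage all donor content is heterozygous
  expect_equal(mean(fr$het_fraction), 2 * mean(fr$donor_fraction))

  # two selfing generations halve heterozygosity twice
  sim2 <- simulate_population(sim_config(n_lines = 250, n_chrom = 4,
                                         markers_per_chrom = 10,
                                         n_selfings = 2, seed = 32))
  fr2 <- truth_genome_fractions(sim2)
  se2 <- sd(fr2$het_fraction) / sqrt(nrow(fr2))
  expect_lt(abs(mean(fr2$het_fraction) - (1 / 8) / 4), 3 * se2)
})

test_that("hybrids carry the parent's introgressions in heterozygous state", {
  cfg <- sim_config(n_lines = 25, n_chrom = 3, markers_per_chrom = 30,
                    make_hybrids = TRUE, seed = 41)
  sim <- simulate_population(cfg)
  expect_true(all(sim$truth_hybrid$zygosity == "heterozygous"))
  # for fully homozygous parents the hybrid coordinates are identical
  het_lines <- unique(sim$truth$line_id[sim$truth$zygosity != "homozygous"])
  fixed <- sim$truth[!sim$truth$line_id %in% het_lines, ]
  hyb <- sim$truth_hybrid[!sim$truth_hybrid$line_id %in% het_lines, ]
  expect_equal(hyb[, c("line_id", "chrom", "start_cM", "end_cM")],
               fixed[, c("line_id", "chrom", "start_cM", "end_cM")])
})

test_that("planted phenotypes follow the additive model exactly at zero noise", {
  cfg <- sim_config(n_lines = 30, n_chrom = 2, markers_per_chrom = 20,
                    noise_sd = 0, seed = 51,
                    planted_qtls = tibble::tibble(trait_id = "t", marker_id = "chr01_m0010",
                                                  effect = 1.5))
  sim <- simulate_bil_study(cfg, null_traits = "nil")
  ph <- sim$phenotypes
  # no QTL, no noise: everything is the baseline
  expect_true(all(ph$value[ph$trait_id == "nil"] == cfg$baseline))
  # class-mean difference equals the planted effect
  calls <- sim$genotypes$chr01_m0010
  hom <- sim$genotypes$line_id[calls == "B"]
  rec <- sim$genotypes$line_id[calls == "A"]
  expect_gt(length(hom), 0)
  vt <- ph[ph$trait_id == "t", ]
  expect_equal(mean(vt$value[vt$line_id %in% hom]) -
                 mean(vt$value[vt$line_id %in% rec]), 1.5)
  # control line sits at baseline
  expect_true(all(vt$value[vt$line_id == "TA209"] == cfg$baseline))
  expect_error(simulate_phenotypes(sim, tibble::tibble(
    trait_id = "x", marker_id = "nope", effect = 1)), "unknown marker")
})

test_that("the default breeding design lands in the expected segment regime", {
  sim <- simulate_population(sim_config(n_lines = 60, markers_per_chrom = 25,
                                        seed = 61))
  seg <- call_introgressions(sim$genotypes, sim$marker_map, sim$chrom_lengths)
  s <- summarize_population(seg, 60, sim$chrom_lengths)
  # BC3 + S10 over 12 ~100-cM chromosomes: a handful of segments per line
  expect_gte(s$mean_segments_per_line, 2)
  expect_lte(s$mean_segments_per_line, 8)
})
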