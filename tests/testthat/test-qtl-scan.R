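make_scan_fixture <- function(seed = 13, n_lines = 60, effect = 2,
                              noise_sd = 0.4) {
  cfg <- sim_config(
    n_lines = n_lines, n_chrom = 3, markers_per_chrom = 15, seed = seed,
    noise_sd = noise_sd,
    planted_qtls = tibble::tibble(trait_id = "met1",
                                  marker_id = "chr02_m0008", effect = effect))
  sim <- simulate_bil_study(cfg, null_traits = "flat1")
  sim$bins <- build_bins(sim$genotypes, sim$marker_map, sim$chrom_lengths)
  sim$true_bin <- sim$bins$bin_id[vapply(sim$bins$marker_ids,
                                         function(x) "chr02_m0008" %in% x, logical(1))]
  sim
}

test_that("a noise-free genotype indicator gives a maximal, tiny-p peak", {
  sim <- make_scan_fixture(noise_sd = 1)
  bg <- bin_genotypes(sim$bins)
  state <- ifelse(unlist(bg[, sim$true_bin]) %in% c("B", "H"), 1, 0)
  expect_gt(length(unique(state)), 1)
  ph <- tibble::tibble(line_id = rep(bg$line_id, 2),
                       trait_id = "ind", replicate = rep(1:2, each = nrow(bg)),
                       value = rep(state, 2) + 5)
  sc <- anova_scan(ph, sim$bins, scan_config(threshold_mode = "bonferroni"))
  cv <- scan_curves(sc)
  peak <- cv$bin_id[which.max(cv$lod)]
  expect_equal(peak, sim$true_bin)
  expect_lt(min(cv$p, na.rm = TRUE), 1e-10)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$effect_direction, "wild_increases")
  expect_equal(sc$effect_size, 1, tolerance = 1e-8)
})

test_that("ANOVA and Haley-Knott LOD coincide at fully observed bins", {
  sim <- make_scan_fixture()
  gm <- build_map(sim$bins)
  cfg <- scan_config(threshold_mode = "none")
  sa <- anova_scan(sim$phenotypes, sim$bins, cfg)
  sh <- hk_scan(sim$phenotypes, sim$bins, gm, cfg)
  ca <- scan_curves(sa)
  ch <- scan_curves(sh)
  # at each bin's own cM position the HK dosage is the 0/1 call itself
  at_bins <- dplyr::inner_join(
    dplyr::semi_join(ch, tibble::as_tibble(gm), by = "bin_id"),
    ca[, c("trait_id", "bin_id", "lod")],
    by = c("trait_id", "bin_id"), suffix = c("_hk", "_anova"))
  at_bins <- at_bins[!is.na(at_bins$lod_anova), ]
  exact <- dplyr::inner_join(at_bins, tibble::as_tibble(gm)[, c("bin_id", "cM")],
                             by = "bin_id")
  exact <- exact[abs(exact$pos_cM - exact$cM) < 1e-9, ]
  expect_gt(nrow(exact), 10)
  expect_equal(exact$lod_hk, exact$lod_anova, tolerance = 1e-8)
})

test_that("both scan methods localise a strong planted QTL", {
  sim <- make_scan_fixture()
  gm <- build_map(sim$bins)
  for (sc in list(
    anova_scan(sim$phenotypes, sim$bins,
               scan_config(threshold_mode = "bonferroni")),
    hk_scan(sim$phenotypes, sim$bins, gm,
            scan_config(threshold_mode = "bonferroni")))) {
    hit <- tidy(sc)[tidy(sc)$trait_id == "met1", ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$peak_bin, sim$true_bin)
    expect_equal(hit$effect_direction, "wild_increases")
    # support interval contains the peak
    expect_lte(hit$interval_start_bp, hit$peak_bp)
    expect_gte(hit$interval_end_bp, hit$peak_bp)
    # the pure-noise trait is not called
    expect_false("flat1" %in% tidy(sc)$trait_id)
  }
})

test_that("LOD support intervals follow the drop rule", {
  curve <- tibble::tibble(
    lod = c(0.1, 0.2, 5, 0.2, 0.1),
    start_bp = c(1, 11, 21, 31, 41), end_bp = c(10, 20, 30, 40, 50))
  iv <- lod_support_interval(curve, 1)
  expect_equal(c(iv$start_bp, iv$end_bp), c(21, 30))   # single-point spike

  tri <- tibble::tibble(
    lod = c(1, 1.5, 2, 2.5, 3, 2.5, 2, 1.5, 1),
    start_bp = 10 * (0:8) + 1, end_bp = 10 * (1:9))
  iv <- lod_support_interval(tri, 1)                    # 0.5/bin -> peak +/- 2
  expect_equal(c(iv$start_bp, iv$end_bp), c(21, 70))

  flat <- tibble::tibble(lod = rep(2, 4), start_bp = c(1, 11, 21, 31),
                         end_bp = c(10, 20, 30, 40))
  expect_warning(iv <- lod_support_interval(flat, 1), "flat")
  expect_equal(c(iv$start_bp, iv$end_bp), c(1, 40))
})

test_that("permutation thresholds are reproducible and seed-controlled", {
  sim <- make_scan_fixture()
  cfg <- scan_config(threshold_mode = "permutation", n_permutations = 120, seed = 99)
  s1 <- anova_scan(sim$phenotypes, sim$bins, cfg)
  s2 <- anova_scan(sim$phenotypes, sim$bins, cfg)
  expect_identical(attr(s1, "thresholds"), attr(s2, "thresholds"))
  expect_true(all(is.finite(attr(s1, "thresholds")$threshold)))
  s3 <- anova_scan(sim$phenotypes, sim$bins,
                   scan_config(threshold_mode = "permutation",
                               n_permutations = 120, seed = 100))
  expect_false(identical(attr(s1, "thresholds")$threshold,
                         attr(s3, "thresholds")$threshold))
})

test_that("peak LOD grows with the planted effect size", {
  seeds <- 101:106
  mean_peak <- vapply(c(0.25, 0.5, 1), function(eff) {
    mean(vapply(seeds, function(s) {
      sim <- make_scan_fixture(seed = s, n_lines = 100, effect = eff,
                               noise_sd = 1)
      cv <- scan_curves(anova_scan(sim$phenotypes, sim$bins,
                                   scan_config(threshold_mode = "none")))
      cv <- cv[cv$trait_id == "met1" & cv$bin_id == sim$true_bin, ]
      cv$lod
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_peak) > 0))
})

test_that("conserved QTL clustering follows interval overlap", {
  q <- tibble::tibble(
    trait_id = "met1", experiment_id = "e1", chrom = "c2",
    peak_bin = "c2.003", peak_bp = 5e6L, lod = 4, p_value = 1e-4,
    effect_size = 1, effect_direction = "wild_increases",
    interval_start_bp = 4e6L, interval_end_bp = 6e6L)
  same <- dplyr::mutate(q, experiment_id = "e2")
  out <- conserved_qtls(q, same)
  expect_true(all(out$conserved))
  expect_equal(out$n_experiments, 2L)

  shifted <- dplyr::mutate(q, experiment_id = "e2",
                           interval_start_bp = 7e6L, interval_end_bp = 9e6L)
  out2 <- conserved_qtls(q, shifted)
  expect_false(any(out2$conserved))
  expect_equal(nrow(out2), 2L)

  other_chrom <- dplyr::mutate(same, chrom = "c3")
  expect_false(any(conserved_qtls(q, other_chrom)$conserved))
})
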