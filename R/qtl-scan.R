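#' Scan configuration
#'
#' @param lod_drop LOD decrease defining support intervals (default 1).
#' @param threshold_mode `"permutation"` (trait-wise permutation of
#'   line means, default), `"bonferroni"`, or `"none"` (report raw
#'   per-bin p-values without calling QTLs; used for calibration
#'   studies).
#' @param n_permutations Permutations per trait (>= 100 when
#'   permutation mode is active).
#' @param alpha Significance level.
#' @param seed Integer seed for the permutation draws (`NULL` leaves
#'   the RNG state untouched).
#' @return A `scan_config` list.
#' @export
scan_config <- function(lod_drop = 1, threshold_mode = c("permutation", "bonferroni", "none"),
                        n_permutations = 1000L, alpha = 0.05, seed = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (lod_drop <= 0) abort("lod_drop must be positive")
  if (threshold_mode == "permutation" && n_permutations < 100) {
    abort("at least 100 permutations are required in permutation mode")
  }
  structure(list(lod_drop = lod_drop, threshold_mode = threshold_mode,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = seed),
            class = "scan_config")
}

# replicate values collapse to line means before any scan: the
# biological replicates are block replicates of a line, not
# independent segregants.
line_trait_means <- function(phenotypes) {
  mm <- dplyr::summarise(dplyr::group_by(phenotypes, .data$line_id, .data$trait_id),
                         value = mean(.data$value), .groups = "drop")
  w <- tidyr::pivot_wider(mm, names_from = "trait_id", values_from = "value")
  Y <- as.matrix(w[, -1, drop = FALSE])
  rownames(Y) <- w$line_id
  Y
}

# evaluate a seeded expression without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# Single-trait single-dosage regressions, vectorised over predictors.
# X: lines x positions dosage matrix (NA = no information);
# y: named line vector.  Returns tibble(n, lod, p, effect) per column.
# With 0/1 dosage this is exactly the two-class one-way ANOVA
# (RSS0 = grand-mean residual SS), so LOD = (n/2) log10(RSS0/RSS1).
regress_cols <- function(y, X) {
  vy <- !is.na(y)
  V <- !is.na(X) & vy
  y0 <- ifelse(vy, y, 0)
  n <- colSums(V)
  X0 <- ifelse(V, X, 0)
  Sy <- colSums(V * y0)
  Syy <- colSums(V * y0^2)
  Sx <- colSums(X0)
  Sxx <- colSums(X0^2)
  Sxy <- colSums(X0 * y0)
  sst <- Syy - Sy^2 / n
  vxx <- Sxx - Sx^2 / n
  vxy <- Sxy - Sx * Sy / n
  ok <- n >= 4 & vxx > 1e-12 & sst > 0
  rss1 <- sst - ifelse(ok, vxy^2 / vxx, 0)
  rss1 <- pmax(rss1, .Machine$double.xmin)
  lod <- ifelse(ok, (n / 2) * log10(sst / rss1), NA_real_)
  fstat <- ifelse(ok, (sst - rss1) / (rss1 / (n - 2)), NA_real_)
  p <- ifelse(ok, pf(fstat, 1, n - 2, lower.tail = FALSE), NA_real_)
  slope <- ifelse(ok, vxy / vxx, NA_real_)
  tibble::tibble(n = as.integer(unname(n)), lod = unname(lod),
                 p = unname(p), effect = unname(slope))
}

# class counts for skip rule: need >= 2 lines in each genotype class
class_ok <- function(y, S) {
  vy <- !is.na(y)
  V <- !is.na(S) & vy
  n1 <- colSums(V * (S == 1), na.rm = TRUE)
  n0 <- colSums(V * (S == 0), na.rm = TRUE)
  n1 >= 2 & n0 >= 2
}

#' Metabolite QTL scan by single-bin ANOVA
#'
#' For every (trait, bin) pair, line means are compared across the two
#' donor-state classes (recurrent `A` versus donor-carrying `B`/`H`;
#' residual heterozygous calls in a homozygous population are grouped
#' with the donor class, and a fully heterozygous hybrid population
#' scans `A` versus `H` through the same collapse).  LOD is
#' `(n/2) log10(RSS0/RSS1)` with `RSS0` the grand-mean residual sum of
#' squares.  Bins with fewer than two lines in either class are
#' skipped.
#'
#' Significant QTLs (per `config$threshold_mode`) are reported one per
#' trait and chromosome at the peak-LOD bin, with a LOD support
#' interval ([lod_support_interval()]) in physical coordinates and the
#' allelic effect direction relative to the wild (donor) allele.
#'
#' @param phenotypes Long phenotype tibble.
#' @param bins A `bil_bins` object.
#' @param config A [scan_config()].
#' @param experiment_id Label carried into the results (e.g. harvest
#'   year or hybrid/inbred set).
#' @return A tibble of class `bil_scan`: one row per detected QTL with
#'   columns `trait_id`, `experiment_id`, `chrom`, `peak_bin`,
#'   `peak_bp`, `lod`, `p_value`, `effect_size`, `effect_direction`,
#'   `interval_start_bp`, `interval_end_bp`.  The full per-bin LOD
#'   curves are attached (see [scan_curves()]), as are the per-trait
#'   thresholds.
#' @export
anova_scan <- function(phenotypes, bins, config = scan_config(),
                       experiment_id = "exp1") {
  bg <- bin_genotypes(bins)
  Y <- line_trait_means(phenotypes)
  miss <- setdiff(rownames(Y), bg$line_id)
  if (length(miss) == nrow(Y)) abort("no phenotyped line is genotyped")
  keep <- intersect(bg$line_id, rownames(Y))
  S <- donor_state(geno_matrix(bg))[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]

  traits <- colnames(Y)
  curves <- vector("list", length(traits))
  thresholds <- rep(NA_real_, length(traits))
  for (ti in seq_along(traits)) {
    y <- Y[, ti]
    ok <- class_ok(y, S)
    X <- S
    X[, !ok] <- NA
    res <- regress_cols(y, X)
    res$lod[!ok] <- NA; res$p[!ok] <- NA; res$effect[!ok] <- NA
    curves[[ti]] <- tibble::tibble(
      trait_id = traits[ti], bin_id = bins$bin_id, chrom = bins$chrom,
      start_bp = bins$start_bp, end_bp = bins$end_bp,
      n = res$n, lod = res$lod, p = res$p, effect = res$effect)
    if (config$threshold_mode == "permutation") {
      thresholds[ti] <- with_local_seed(
        if (is.null(config$seed)) NULL else config$seed + ti,
        perm_threshold(y, S[, ok, drop = FALSE], config))
    }
  }
  curves <- dplyr::bind_rows(curves)
  assemble_scan(curves, bins, config, experiment_id, thresholds, traits,
                method = "anova")
}

# trait-wise permutation null: max LOD over bins for shuffled line means
perm_threshold <- function(y, S, config) {
  v <- which(!is.na(y))
  if (length(v) < 4 || ncol(S) == 0) return(Inf)
  maxlod <- vapply(seq_len(config$n_permutations), function(i) {
    yp <- y
    yp[v] <- y[sample(v)]
    max(regress_cols(yp, S)$lod, na.rm = TRUE)
  }, numeric(1))
  as.numeric(quantile(maxlod, 1 - config$alpha, names = FALSE, type = 7))
}

# shared QTL-table assembly for anova and HK scans.  `curves` must
# carry trait_id, chrom, bin_id, start_bp, end_bp, lod, p, effect and
# (for HK) pos_bp/group columns.
assemble_scan <- function(curves, bins, config, experiment_id, thresholds,
                          traits, method, group_col = "chrom") {
  qtl <- list()
  for (ti in seq_along(traits)) {
    tc <- curves[curves$trait_id == traits[ti], , drop = FALSE]
    # bonferroni counts bins, not grid points: interior HK positions
    # interpolate the same bin data and are not extra tests
    n_tests <- if ("bin_id" %in% names(tc)) {
      length(unique(tc$bin_id[!is.na(tc$p)]))
    } else {
      sum(!is.na(tc$p))
    }
    sig <- switch(config$threshold_mode,
      none = rep(FALSE, nrow(tc)),
      bonferroni = !is.na(tc$p) & tc$p <= config$alpha / max(n_tests, 1L),
      permutation = !is.na(tc$lod) & tc$lod >= thresholds[ti])
    if (!any(sig)) next
    for (grp in unique(tc[[group_col]][sig])) {
      gc <- tc[tc[[group_col]] == grp, , drop = FALSE]
      gsig <- sig[tc[[group_col]] == grp]
      if (!any(gsig)) next
      peak <- which(gc$lod == max(gc$lod[gsig], na.rm = TRUE))[1]
      iv <- lod_support_interval(gc, config$lod_drop, peak = peak)
      peak_bp <- if ("pos_bp" %in% names(gc)) gc$pos_bp[peak] else
        as.integer(round((gc$start_bp[peak] + gc$end_bp[peak]) / 2))
      qtl[[length(qtl) + 1L]] <- tibble::tibble(
        trait_id = traits[ti], experiment_id = experiment_id,
        chrom = gc$chrom[1],
        peak_bin = if ("bin_id" %in% names(gc)) gc$bin_id[peak] else NA_character_,
        peak_bp = peak_bp,
        lod = gc$lod[peak], p_value = gc$p[peak],
        effect_size = gc$effect[peak],
        effect_direction = if (gc$effect[peak] >= 0) "wild_increases" else "wild_decreases",
        interval_start_bp = iv$start_bp, interval_end_bp = iv$end_bp)
    }
  }
  out <- if (length(qtl)) dplyr::bind_rows(qtl) else tibble::tibble(
    trait_id = character(), experiment_id = character(), chrom = character(),
    peak_bin = character(), peak_bp = integer(), lod = numeric(),
    p_value = numeric(), effect_size = numeric(), effect_direction = character(),
    interval_start_bp = integer(), interval_end_bp = integer())
  attr(out, "curves") <- curves
  attr(out, "thresholds") <- tibble::tibble(trait_id = traits, threshold = thresholds)
  attr(out, "config") <- config
  attr(out, "method") <- method
  class(out) <- c("bil_scan", class(out))
  out
}

#' Per-position LOD curves of a scan
#'
#' @param scan A `bil_scan` object.
#' @return The full curve tibble (all traits, all bins or grid
#'   positions, including non-significant ones).
#' @export
scan_curves <- function(scan) {
  cv <- attr(scan, "curves")
  if (is.null(cv)) abort("not a scan object with attached curves")
  cv
}

#' LOD support interval around a peak
#'
#' The maximal contiguous region around the peak in which the LOD
#' stays within `lod_drop` of the peak LOD, reported in physical
#' coordinates.  Positions with no LOD (skipped bins) terminate the
#' expansion.  A flat curve returns the whole extent with a warning.
#'
#' @param curve Tibble for a single chromosome or linkage group, in
#'   positional order, with columns `lod`, `start_bp`, `end_bp`.
#' @param lod_drop LOD decrease (default 1).
#' @param peak Index of the peak position; defaults to the argmax.
#' @return One-row tibble: `start_bp`, `end_bp`.
#' @export
lod_support_interval <- function(curve, lod_drop = 1, peak = NULL) {
  lod <- curve$lod
  if (all(is.na(lod))) abort("curve has no LOD values")
  if (is.null(peak)) peak <- which.max(lod)
  finite <- !is.na(lod)
  if (length(unique(lod[finite])) == 1L && sum(finite) == length(lod)) {
    warn("flat LOD curve; returning the whole extent")
    return(tibble::tibble(start_bp = min(curve$start_bp),
                          end_bp = max(curve$end_bp)))
  }
  thr <- lod[peak] - lod_drop
  lo <- peak
  while (lo > 1 && !is.na(lod[lo - 1]) && lod[lo - 1] >= thr) lo <- lo - 1
  hi <- peak
  while (hi < length(lod) && !is.na(lod[hi + 1]) && lod[hi + 1] >= thr) hi <- hi + 1
  tibble::tibble(start_bp = curve$start_bp[lo], end_bp = curve$end_bp[hi])
}

#' Metabolite QTL scan by Haley-Knott regression
#'
#' Scans each linkage group on a cM grid.  At every grid position the
#' expected donor dosage of each line is computed from its nearest
#' informative flanking bin calls and the intervening recombination
#' fractions under a no-interference two-point model (Markov chain on
#' donor state; lines with no informative flank are excluded, lines
#' with a single flank use the one-sided transition probability).
#' Line means are regressed on the expected dosage and the LOD derives
#' from the regression residual sums of squares exactly as in
#' [anova_scan()]; at a fully observed bin position the dosage is the
#' 0/1 call itself and the two scans coincide.
#'
#' Single-bin linkage groups carry no flanking information and
#' collapse to the single-bin ANOVA.  QTLs are reported one per trait
#' and linkage group.
#'
#' @inheritParams anova_scan
#' @param genetic_map A `bil_map` from [build_map()] for the same
#'   bins.
#' @param step_cM Grid step inside bin intervals (bin positions are
#'   always included).
#' @return A `bil_scan` tibble (see [anova_scan()]); curves carry
#'   `pos_cM`, `pos_bp` and `group` columns.
#' @export
hk_scan <- function(phenotypes, bins, genetic_map, config = scan_config(),
                    experiment_id = "exp1", step_cM = 1) {
  bg <- bin_genotypes(bins)
  Y <- line_trait_means(phenotypes)
  keep <- intersect(bg$line_id, rownames(Y))
  if (!length(keep)) abort("no phenotyped line is genotyped")
  S <- donor_state(geno_matrix(bg))[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  mf <- attr(genetic_map, "map_function") %||% "haldane"
  binfo <- dplyr::left_join(genetic_map, bins[, c("bin_id", "start_bp", "end_bp")],
                            by = "bin_id")
  binfo$mid_bp <- (binfo$start_bp + binfo$end_bp) / 2

  grids <- list()
  for (grp in unique(binfo$group)) {
    gb <- binfo[binfo$group == grp, , drop = FALSE]
    cms <- gb$cM
    grid <- if (nrow(gb) == 1L) cms else
      sort(unique(c(cms, seq(min(cms), max(cms), by = step_cM))))
    X <- hk_dosage(S[, gb$bin_id, drop = FALSE], cms, grid, mf)
    pos_bp <- grid_to_bp(grid, gb)
    grids[[grp]] <- list(gb = gb, grid = grid, X = X, pos_bp = pos_bp)
  }

  traits <- colnames(Y)
  curves <- vector("list", length(traits))
  thresholds <- rep(NA_real_, length(traits))
  Xall <- do.call(cbind, lapply(grids, `[[`, "X"))
  for (ti in seq_along(traits)) {
    y <- Y[, ti]
    res <- regress_cols(y, Xall)
    off <- 0L
    cur <- list()
    for (grp in names(grids)) {
      g <- grids[[grp]]
      npos <- length(g$grid)
      idx <- off + seq_len(npos)
      off <- off + npos
      nearest <- vapply(g$grid, function(p) which.min(abs(g$gb$cM - p)), integer(1))
      cur[[grp]] <- tibble::tibble(
        trait_id = traits[ti], group = grp, chrom = g$gb$chrom[1],
        bin_id = g$gb$bin_id[nearest], pos_cM = g$grid,
        pos_bp = as.integer(round(g$pos_bp)),
        start_bp = g$gb$start_bp[nearest], end_bp = g$gb$end_bp[nearest],
        n = res$n[idx], lod = res$lod[idx], p = res$p[idx], effect = res$effect[idx])
    }
    curves[[ti]] <- dplyr::bind_rows(cur)
    if (config$threshold_mode == "permutation") {
      thresholds[ti] <- with_local_seed(
        if (is.null(config$seed)) NULL else config$seed + ti,
        perm_threshold(y, Xall, config))
    }
  }
  curves <- dplyr::bind_rows(curves)
  assemble_scan(curves, bins, config, experiment_id, thresholds, traits,
                method = "hk", group_col = "group")
}

# Expected donor dosage at grid positions from flanking bin calls.
# S: lines x bins 0/1/NA donor states for one linkage group, in cM
# order; cms: bin cM positions; grid: query positions.
hk_dosage <- function(S, cms, grid, map_function = "haldane") {
  n <- nrow(S)
  X <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    obs <- which(!is.na(S[i, ]))
    if (!length(obs)) next
    op <- cms[obs]
    g <- S[i, obs]
    li <- findInterval(grid, op)
    ri <- li + 1L
    at <- rep(FALSE, length(grid))
    hit <- which(li >= 1L)
    at[hit] <- abs(grid[hit] - op[li[hit]]) < 1e-9
    ri[at] <- li[at]
    for (j in seq_along(grid)) {
      L <- li[j]; R <- ri[j]
      hasL <- L >= 1L
      hasR <- R <= length(obs)
      if (hasL && hasR && L == R) {
        X[i, j] <- g[L]
      } else if (hasL && hasR) {
        r1 <- rf_from_distance(grid[j] - op[L], map_function)
        r2 <- rf_from_distance(op[R] - grid[j], map_function)
        r12 <- r1 + r2 - 2 * r1 * r2
        t1 <- if (g[L] == 1) 1 - r1 else r1        # P(gL -> donor)
        t2 <- if (g[R] == 1) 1 - r2 else r2        # P(donor -> gR)
        t12 <- if (g[L] == g[R]) 1 - r12 else r12  # P(gL -> gR)
        X[i, j] <- t1 * t2 / t12
      } else if (hasL) {
        r1 <- rf_from_distance(grid[j] - op[L], map_function)
        X[i, j] <- if (g[L] == 1) 1 - r1 else r1
      } else if (hasR) {
        r2 <- rf_from_distance(op[R] - grid[j], map_function)
        X[i, j] <- if (g[R] == 1) 1 - r2 else r2
      }
    }
  }
  X
}

# piecewise-linear cM -> bp through bin (cM, midpoint bp) anchors,
# extended to the terminal bins' physical tips
grid_to_bp <- function(grid, gb) {
  if (nrow(gb) == 1L) return(rep((gb$start_bp + gb$end_bp) / 2, length(grid)))
  anchors_cm <- gb$cM
  anchors_bp <- gb$mid_bp
  bp <- stats::approx(anchors_cm, anchors_bp, xout = grid, rule = 2, ties = "ordered")$y
  bp
}

#' Cross-experiment conserved QTLs
#'
#' Same-trait QTLs whose support intervals intersect on the same
#' chromosome are clustered (transitively, by interval overlap); a
#' cluster spanning at least two distinct experiments is conserved.
#'
#' @param ... `bil_scan` result tibbles (or plain tibbles with the
#'   same columns), each carrying its `experiment_id`.
#' @return Tibble with one row per overlap cluster: `trait_id`,
#'   `chrom`, `interval_start_bp`, `interval_end_bp` (cluster bounds),
#'   `n_experiments`, `experiments`, `n_qtls`, `conserved`.
#' @export
conserved_qtls <- function(...) {
  scans <- list(...)
  if (length(scans) == 1L && is.list(scans[[1]]) && !is.data.frame(scans[[1]])) {
    scans <- scans[[1]]
  }
  if (length(scans) < 2L) abort("need results from at least two experiments")
  all_q <- dplyr::bind_rows(lapply(scans, function(s) tibble::as_tibble(unclass_scan(s))))
  if (!nrow(all_q)) return(tibble::tibble(
    trait_id = character(), chrom = character(), interval_start_bp = integer(),
    interval_end_bp = integer(), n_experiments = integer(),
    experiments = character(), n_qtls = integer(), conserved = logical()))
  out <- dplyr::group_modify(
    dplyr::group_by(all_q, .data$trait_id, .data$chrom),
    function(df, key) {
      o <- order(df$interval_start_bp, df$interval_end_bp)
      df <- df[o, ]
      cl <- integer(nrow(df)); cl[1] <- 1L
      hi <- df$interval_end_bp[1]
      for (i in seq_len(nrow(df))[-1]) {
        if (df$interval_start_bp[i] <= hi) {
          cl[i] <- cl[i - 1]
          hi <- max(hi, df$interval_end_bp[i])
        } else {
          cl[i] <- cl[i - 1] + 1L
          hi <- df$interval_end_bp[i]
        }
      }
      dplyr::summarise(dplyr::group_by(df, cluster = cl),
        interval_start_bp = min(.data$interval_start_bp),
        interval_end_bp = max(.data$interval_end_bp),
        n_experiments = dplyr::n_distinct(.data$experiment_id),
        experiments = paste(sort(unique(.data$experiment_id)), collapse = ","),
        n_qtls = dplyr::n(), .groups = "drop")
    })
  out <- dplyr::ungroup(out)
  out$cluster <- NULL
  out$conserved <- out$n_experiments >= 2L
  out
}

unclass_scan <- function(s) {
  attr(s, "curves") <- NULL
  attr(s, "thresholds") <- NULL
  attr(s, "config") <- NULL
  attr(s, "method") <- NULL
  class(s) <- c("tbl_df", "tbl", "data.frame")
  s
}

#' @export
tidy.bil_scan <- function(x, ...) tibble::as_tibble(unclass_scan(x))

#' @export
glance.bil_scan <- function(x, ...) {
  cv <- attr(x, "curves")
  tibble::tibble(
    n_qtls = nrow(x),
    n_traits = length(unique(cv$trait_id)),
    n_positions = nrow(cv) / max(length(unique(cv$trait_id)), 1L),
    method = attr(x, "method") %||% NA_character_
  )
}
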