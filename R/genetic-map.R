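#' Estimate the recombination fraction between two bins
#'
#' Calls are collapsed to donor state (`B`/`H` -> donor, `A` ->
#' recurrent, `U` -> missing).  The estimate is the fraction of lines,
#' among those non-missing in both bins, whose donor states differ,
#' capped at 0.5; each line counts as one recombination opportunity.
#' `rf` is undefined (`NA`) when no line is non-missing in both bins.
#'
#' Note this is a line-level discordance fraction, not a per-meiosis
#' rate: repeated backcrossing and selfing both expand (through extra
#' meioses) and dilute (through donor loss) the observable
#' recombination signal, so cM from these rf values are an internally
#' consistent relative scale rather than single-meiosis distances.
#' The estimator is symmetric in its arguments and invariant to line
#' relabelling.
#'
#' @param binA_column,binB_column Same-length per-line call vectors.
#' @return One-row tibble: `rf` (in `[0, 0.5]`, `NA` when undefined),
#'   `n_informative` (lines non-missing in both bins) and
#'   `n_bridging` (lines carrying donor in both bins — the lines whose
#'   segments physically bridge the interval; zero means the interval
#'   is a donor-coverage gap and carries no linkage, see
#'   [build_map()]).
#' @export
estimate_rf <- function(binA_column, binB_column) {
  stopifnot(length(binA_column) == length(binB_column))
  a <- donor_state(binA_column)
  b <- donor_state(binB_column)
  both <- !is.na(a) & !is.na(b)
  n <- sum(both)
  rf <- if (n == 0) NA_real_ else min(sum(a[both] != b[both]) / n, 0.5)
  tibble::tibble(rf = rf, n_informative = as.integer(n),
                 n_bridging = as.integer(sum(both & a == 1 & b == 1)))
}

#' Convert a recombination fraction to map distance
#'
#' Haldane (no interference): d = -50 ln(1 - 2r).  Kosambi:
#' d = 25 ln((1 + 2r) / (1 - 2r)).  An rf at or above 0.5 maps to
#' `Inf`, the signal used to split linkage groups.
#'
#' @param rf Recombination fraction(s) in `[0, 0.5]`.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Distance(s) in centiMorgans.
#' @export
map_distance <- function(rf, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(rf < 0 | rf > 0.5, na.rm = TRUE)) abort("rf must lie in [0, 0.5]")
  d <- switch(map_function,
    haldane = -50 * log(1 - 2 * rf),
    kosambi = 25 * log((1 + 2 * rf) / (1 - 2 * rf))
  )
  d[!is.na(rf) & rf >= 0.5] <- Inf
  d
}

# inverse map function: cM -> rf
rf_from_distance <- function(d_cM, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  switch(map_function,
    haldane = (1 - exp(-2 * d_cM / 100)) / 2,
    kosambi = tanh(2 * d_cM / 100) / 2
  )
}

#' Build a bin-level genetic map
#'
#' Chains adjacent-bin recombination fractions into cumulative cM
#' positions along each chromosome.  A new linkage group starts
#' wherever linkage information is absent: the rf is undefined, no
#' line's donor segment bridges the interval (donor-coverage gap), or
#' the rf reaches 0.5.  Single-bin groups are permitted — they carry
#' no internal linkage information and exist only on the physical
#' scale; incomplete donor coverage of the genome therefore yields
#' more linkage groups than chromosomes.
#'
#' @param bins A `bil_bins` object from [build_bins()] (its attached
#'   consensus genotypes provide the rf data).
#' @param map_function Map function passed to [map_distance()].
#' @return A tibble of class `bil_map`: `group`, `chrom`, `bin_id`,
#'   `cM` (cumulative within group), `rf_prev`, `n_informative`
#'   (interval to the previous bin; `NA` for the first bin of a
#'   group).  [glance()] returns the total map length, group count and
#'   bin count.
#' @export
build_map <- function(bins, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  bg <- bin_genotypes(bins)
  state <- donor_state(geno_matrix(bg))
  groups <- character(nrow(bins))
  cm <- numeric(nrow(bins))
  rf_prev <- rep(NA_real_, nrow(bins))
  n_inf <- rep(NA_integer_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    g <- 1L; pos <- 0
    groups[idx[1]] <- sprintf("%s.%d", ch, g)
    for (k in seq_along(idx)[-1]) {
      i <- idx[k]; prev <- idx[k - 1]
      a <- state[, bins$bin_id[prev]]
      b <- state[, bins$bin_id[i]]
      both <- !is.na(a) & !is.na(b)
      n <- sum(both)
      rf <- if (n == 0) NA_real_ else min(sum(a[both] != b[both]) / n, 0.5)
      bridged <- any(both & a == 1 & b == 1)
      rf_prev[i] <- rf
      n_inf[i] <- as.integer(n)
      d <- if (is.na(rf) || !bridged) Inf else map_distance(rf, map_function)
      if (!is.finite(d)) {
        g <- g + 1L; pos <- 0
      } else {
        pos <- pos + d
      }
      groups[i] <- sprintf("%s.%d", ch, g)
      cm[i] <- pos
    }
  }
  out <- tibble::tibble(group = groups, chrom = bins$chrom,
                        bin_id = bins$bin_id, cM = cm,
                        rf_prev = rf_prev, n_informative = n_inf)
  attr(out, "map_function") <- map_function
  class(out) <- c("bil_map", class(out))
  out
}

#' @export
glance.bil_map <- function(x, ...) {
  per_group <- tapply(x$cM, x$group, max)
  tibble::tibble(
    total_length_cM = sum(per_group),
    n_groups = length(per_group),
    n_bins = nrow(x)
  )
}
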