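#' Partition markers into co-segregation bins
#'
#' A bin is a maximal run of adjacent markers whose genotype columns
#' are identical across the whole population, i.e. no recombination
#' event falls between them in any line.  Missing calls are wildcards:
#' a `U` is compatible with any call, so sporadic missing data does not
#' shatter bins.  Merging is a greedy left-to-right scan anchored on
#' the running per-line consensus (compatibility is not transitive
#' under wildcards, so the anchored scan is the deterministic choice).
#'
#' Bin physical intervals tile each chromosome completely: the boundary
#' between two adjacent bins is the floor midpoint between their
#' bounding markers (consistent with introgression borders), and
#' terminal bins extend to the chromosome tips.
#'
#' @param geno Genotype tibble.
#' @param marker_map Marker map tibble.
#' @param chrom_lengths Chromosome-length tibble.
#' @return A tibble of class `bil_bins` with columns `bin_id`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps` and a list-column `marker_ids`.
#'   The per-line consensus calls are attached as a genotype tibble
#'   (`line_id` + one column per bin) retrievable with
#'   [bin_genotypes()].
#' @export
build_bins <- function(geno, marker_map, chrom_lengths) {
  marker_map <- validate_marker_map(marker_map)
  geno <- validate_genotypes(geno, marker_map)
  validate_chrom_lengths(marker_map, chrom_lengths)
  m <- geno_matrix(geno)
  len <- setNames(chrom_lengths$length_bp, chrom_lengths$chrom)
  chroms <- unique(marker_map$chrom)

  bin_rows <- list()
  consensus_cols <- list()
  for (ch in chroms) {
    sel <- which(marker_map$chrom == ch)
    pos <- marker_map$pos_bp[sel]
    ids <- marker_map$marker_id[sel]
    sub <- m[, sel, drop = FALSE]
    # greedy scan: merge marker j into the open bin iff its column is
    # compatible (equal or one side missing) with the running consensus
    first <- integer(0); last <- integer(0)
    cons <- list()
    cur_first <- 1L
    cur_cons <- sub[, 1L]
    nm <- length(sel)
    j <- 2L
    while (j <= nm + 1L) {
      compatible <- if (j <= nm) {
        col <- sub[, j]
        all(cur_cons == col | cur_cons == "U" | col == "U")
      } else FALSE
      if (compatible) {
        fill <- cur_cons == "U"
        cur_cons[fill] <- col[fill]
      } else {
        first <- c(first, cur_first); last <- c(last, j - 1L)
        cons[[length(cons) + 1L]] <- cur_cons
        if (j <= nm) {
          cur_first <- j
          cur_cons <- sub[, j]
        }
      }
      j <- j + 1L
    }
    nb <- length(first)
    # physical bounds: floor-midpoint boundaries, tips at the ends
    bnd <- if (nb > 1L) floor((pos[last[-nb]] + pos[first[-1L]]) / 2) else numeric(0)
    start_bp <- as.integer(c(1, bnd + 1))
    end_bp <- as.integer(c(bnd, len[[ch]]))
    bin_rows[[ch]] <- tibble::tibble(
      bin_id = sprintf("%s.%03d", ch, seq_len(nb)),
      chrom = ch, start_bp = start_bp, end_bp = end_bp,
      n_snps = last - first + 1L,
      marker_ids = lapply(seq_len(nb), function(k) ids[first[k]:last[k]])
    )
    consensus_cols[[ch]] <- do.call(cbind, cons)
  }
  bins <- dplyr::bind_rows(bin_rows)
  cons_mat <- do.call(cbind, consensus_cols)
  colnames(cons_mat) <- bins$bin_id
  bg <- tibble::as_tibble(as.data.frame(cons_mat, stringsAsFactors = FALSE))
  bg <- dplyr::bind_cols(tibble::tibble(line_id = geno$line_id), bg)
  attr(bins, "genotypes") <- bg
  class(bins) <- c("bil_bins", class(bins))
  bins
}

#' Extract the lines-by-bins consensus genotype table
#'
#' @param bins A `bil_bins` object from [build_bins()].
#' @return Tibble: `line_id` plus one call column per bin, in the same
#'   `{A,B,H,U}` alphabet as the marker-level genotypes (`U` where all
#'   of a line's calls in the bin are missing).
#' @export
bin_genotypes <- function(bins) {
  bg <- attr(bins, "genotypes")
  if (is.null(bg)) {
    abort("no genotype attribute; pass the object returned by build_bins()")
  }
  bg
}

#' Bin-level summary statistics
#'
#' @param bins A `bil_bins` tibble (or any tibble with `start_bp`,
#'   `end_bp`, `n_snps`).
#' @return One-row tibble: `n_bins`, `mean_length_bp`,
#'   `mean_snps_per_bin`.
#' @export
bin_summary <- function(bins) {
  if (!nrow(bins)) abort("empty bin list")
  tibble::tibble(
    n_bins = nrow(bins),
    mean_length_bp = mean(bins$end_bp - bins$start_bp + 1),
    mean_snps_per_bin = mean(bins$n_snps)
  )
}

#' @export
glance.bil_bins <- function(x, ...) bin_summary(x)
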