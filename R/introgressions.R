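#' Call donor introgression segments for one chromosome
#'
#' Converts a position-sorted vector of genotype calls into donor
#' segments.  A segment is a maximal run of donor-informative calls
#' (`B` or `H`); missing calls (`U`) are transparent — they neither
#' break nor extend a run.  Interior borders are placed half-way
#' (integer floor) between the outermost donor-informative marker and
#' the nearest flanking recurrent (`A`) marker.  If a run reaches the
#' first or last informative marker of the chromosome, the border is
#' extended to the chromosome tip (position 1 or `chrom_length`).
#'
#' @param calls Character vector of calls in `{A,B,H,U}`.
#' @param pos_bp Integer marker positions (strictly increasing).
#' @param chrom_length Chromosome length in bp.
#' @return Tibble with columns `start_bp`, `end_bp`, `zygosity`
#'   (`homozygous` if all run calls are `B`, `heterozygous` if all `H`,
#'   else `mixed`) and `n_markers` (donor-informative markers in the
#'   run).  Zero rows when no donor allele is present; a chromosome
#'   with no informative call at all yields zero rows with a warning.
#' @export
call_segments <- function(calls, pos_bp, chrom_length) {
  stopifnot(length(calls) == length(pos_bp))
  empty <- tibble::tibble(start_bp = integer(), end_bp = integer(),
                          zygosity = character(), n_markers = integer())
  inf_idx <- which(calls != "U")
  if (!length(inf_idx)) {
    warn("chromosome with zero non-missing calls; no segments called")
    return(empty)
  }
  ic <- calls[inf_idx]
  ip <- pos_bp[inf_idx]
  donor <- ic %in% c("B", "H")
  if (!any(donor)) return(empty)
  r <- rle(donor)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    i1 <- starts[k]; i2 <- ends[k]
    start_bp <- if (i1 == 1L) 1L else
      as.integer(floor((ip[i1 - 1L] + ip[i1]) / 2))
    end_bp <- if (i2 == length(ic)) as.integer(chrom_length) else
      as.integer(floor((ip[i2] + ip[i2 + 1L]) / 2))
    run <- ic[i1:i2]
    zyg <- if (all(run == "B")) "homozygous"
           else if (all(run == "H")) "heterozygous" else "mixed"
    tibble::tibble(start_bp = start_bp, end_bp = end_bp,
                   zygosity = zyg, n_markers = i2 - i1 + 1L)
  })
  dplyr::bind_rows(out)
}

#' Call introgression segments for a whole population
#'
#' Applies [call_segments()] to every line and chromosome of a
#' genotype matrix.
#'
#' @param geno Genotype tibble (see [read_genotypes()]).
#' @param marker_map Marker map tibble.
#' @param chrom_lengths Chromosome-length tibble.
#' @return Tibble with columns `line_id`, `chrom`, `start_bp`,
#'   `end_bp`, `zygosity`, `n_markers`, `length_bp`.
#' @export
call_introgressions <- function(geno, marker_map, chrom_lengths) {
  marker_map <- validate_marker_map(marker_map)
  geno <- validate_genotypes(geno, marker_map)
  validate_chrom_lengths(marker_map, chrom_lengths)
  m <- geno_matrix(geno)
  len <- setNames(chrom_lengths$length_bp, chrom_lengths$chrom)
  chroms <- unique(marker_map$chrom)
  res <- lapply(chroms, function(ch) {
    sel <- marker_map$chrom == ch
    pos <- marker_map$pos_bp[sel]
    sub <- m[, sel, drop = FALSE]
    per_line <- lapply(rownames(sub), function(ln) {
      seg <- call_segments(sub[ln, ], pos, len[[ch]])
      if (nrow(seg)) tibble::tibble(line_id = ln, chrom = ch, seg) else NULL
    })
    dplyr::bind_rows(per_line)
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    return(tibble::tibble(line_id = character(), chrom = character(),
                          start_bp = integer(), end_bp = integer(),
                          zygosity = character(), n_markers = integer(),
                          length_bp = integer()))
  }
  out$length_bp <- out$end_bp - out$start_bp + 1L
  dplyr::arrange(out, match(.data$line_id, geno$line_id),
                 match(.data$chrom, chroms), .data$start_bp)
}

#' Population-level introgression statistics
#'
#' Summaries of the donor content of a BIL population: how many lines
#' carry at least one introgression, segments per line, per-line summed
#' segment length, and the fraction of the genome covered by the union
#' of all segments across lines.  Per-line means and medians are taken
#' over lines with at least one segment; lines without any segment are
#' counted but excluded from those means.
#'
#' @param segments Segment tibble from [call_introgressions()].
#' @param n_lines_total Total number of genotyped lines (including
#'   lines without any introgression).
#' @param chrom_lengths Chromosome-length tibble (defines the total
#'   genome length for the coverage fraction).
#' @return One-row tibble with columns `n_lines_total`,
#'   `n_lines_with_segment`, `n_lines_without`,
#'   `mean_segments_per_line`, `max_segments_per_line`,
#'   `mean_sum_length_bp`, `median_sum_length_bp`,
#'   `mean_segment_length_bp`, `genome_coverage_fraction`.
#' @export
summarize_population <- function(segments, n_lines_total, chrom_lengths) {
  if (!nrow(segments)) {
    return(tibble::tibble(
      n_lines_total = as.integer(n_lines_total), n_lines_with_segment = 0L,
      n_lines_without = as.integer(n_lines_total),
      mean_segments_per_line = NA_real_, max_segments_per_line = NA_integer_,
      mean_sum_length_bp = NA_real_, median_sum_length_bp = NA_real_,
      mean_segment_length_bp = NA_real_, genome_coverage_fraction = 0))
  }
  seg_len <- segments$end_bp - segments$start_bp + 1
  per_line <- dplyr::summarise(dplyr::group_by(segments, .data$line_id),
                               n_seg = dplyr::n(),
                               sum_len = sum(.data$end_bp - .data$start_bp + 1),
                               .groups = "drop")
  covered <- sum(vapply(split(segments, segments$chrom), function(s) {
    merged_interval_length(s$start_bp, s$end_bp)
  }, numeric(1)))
  tibble::tibble(
    n_lines_total = as.integer(n_lines_total),
    n_lines_with_segment = nrow(per_line),
    n_lines_without = as.integer(n_lines_total) - nrow(per_line),
    mean_segments_per_line = mean(per_line$n_seg),
    max_segments_per_line = max(per_line$n_seg),
    mean_sum_length_bp = mean(per_line$sum_len),
    median_sum_length_bp = median(per_line$sum_len),
    mean_segment_length_bp = mean(seg_len),
    genome_coverage_fraction = covered / sum(chrom_lengths$length_bp)
  )
}

# total length of the union of closed integer intervals
merged_interval_length <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1)
}
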