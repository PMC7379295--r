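# Independent reference implementations used as oracles.  These are
# deliberately written as plain index-walking loops, separate from the
# vectorised package code paths they check.

# Segment caller oracle: walk markers one by one, tracking the last
# informative recurrent marker and open donor runs; apply the midpoint
# and chromosome-tip border rules directly.
oracle_segments <- function(calls, pos, chrom_len) {
  runs <- list()
  open_first <- NA_integer_
  open_last <- NA_integer_
  last_A <- NA_integer_
  for (i in seq_along(calls)) {
    ci <- calls[i]
    if (ci == "U") next
    if (ci == "A") {
      if (!is.na(open_first)) {
        runs[[length(runs) + 1]] <- list(first = open_first, last = open_last,
                                         prev_A = last_A, next_A = i)
        open_first <- NA_integer_
      }
      last_A <- i
    } else {
      if (is.na(open_first)) open_first <- i
      open_last <- i
    }
  }
  if (!is.na(open_first)) {
    runs[[length(runs) + 1]] <- list(first = open_first, last = open_last,
                                     prev_A = last_A, next_A = NA_integer_)
  }
  out <- data.frame(start_bp = integer(0), end_bp = integer(0),
                    zygosity = character(0), n_markers = integer(0))
  for (r in runs) {
    s <- if (is.na(r$prev_A)) 1L else as.integer(floor((pos[r$prev_A] + pos[r$first]) / 2))
    e <- if (is.na(r$next_A)) as.integer(chrom_len) else
      as.integer(floor((pos[r$last] + pos[r$next_A]) / 2))
    run_calls <- calls[r$first:r$last]
    run_calls <- run_calls[run_calls != "U"]
    z <- if (all(run_calls == "B")) "homozygous"
         else if (all(run_calls == "H")) "heterozygous" else "mixed"
    out <- rbind(out, data.frame(start_bp = s, end_bp = e, zygosity = z,
                                 n_markers = length(run_calls)))
  }
  out
}

# Haley-Knott dosage oracle: exhaustively enumerate the donor-state
# paths of a 3-locus Markov chain (left flank, query, right flank) and
# take the conditional expectation of the query state.
oracle_hk_dosage <- function(gL, gR, r1, r2) {
  num <- 0; den <- 0
  for (gQ in c(0, 1)) {
    t1 <- if (gL == gQ) 1 - r1 else r1
    t2 <- if (gQ == gR) 1 - r2 else r2
    p <- t1 * t2
    den <- den + p
    num <- num + p * gQ
  }
  num / den
}

# small fixture builders -------------------------------------------------

toy_map <- function(pos_bp, chrom = "c1") {
  tibble::tibble(marker_id = sprintf("%s_m%02d", chrom, seq_along(pos_bp)),
                 chrom = chrom, pos_bp = as.integer(pos_bp))
}

toy_geno <- function(map, ...) {
  rows <- list(...)
  calls <- do.call(rbind, rows)
  colnames(calls) <- map$marker_id
  dplyr::bind_cols(
    tibble::tibble(line_id = names(rows) %||% sprintf("L%02d", seq_along(rows))),
    tibble::as_tibble(as.data.frame(calls, stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
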