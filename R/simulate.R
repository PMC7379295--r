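#' Simulation configuration for the BIL breeding scheme
#'
#' Defaults emulate the study design the package targets: an
#' interspecific F1 backcrossed three times to the recurrent parent,
#' then selfed ten generations by single-seed descent, over a
#' 12-chromosome genome of ~100 cM / 65 Mbp per chromosome genotyped
#' at SolCAP-like density (~260 markers per chromosome), with 141
#' lines and three biological replicates per phenotype.
#'
#' @param n_lines Number of independent BILs to derive.
#' @param n_chrom,markers_per_chrom,chrom_len_cM,chrom_len_bp Genome
#'   and marker-panel geometry for the auto-generated map (ignored
#'   when `marker_map`/`chrom_lengths` are supplied).
#' @param marker_map,chrom_lengths Optional explicit map.  `marker_map`
#'   may carry a `pos_cM` column; otherwise cM positions are linear in
#'   bp.
#' @param n_backcrosses,n_selfings Breeding-scheme depth.
#' @param make_hybrids Also cross each finished line back to the
#'   recurrent parent, yielding a fully heterozygous hybrid set.
#' @param missing_rate Per-call probability of emitting `U`.
#' @param planted_qtls Tibble (`trait_id`, `marker_id`, `effect`,
#'   optional `dominance`) of additive QTLs for
#'   [simulate_phenotypes()]; effects are in trait units (equal to
#'   phenotypic SD units at the default `noise_sd = 1`).
#' @param n_replicates,noise_sd,baseline Phenotype model: replicate
#'   value = baseline + sum(effect x donor dosage) + N(0, noise_sd).
#' @param control_line_id Line id given to the simulated recurrent
#'   parent in phenotype tables.
#' @param seed Mandatory integer seed; with it fixed, all outputs are
#'   byte-identical across runs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_lines = 141L, n_chrom = 12L, markers_per_chrom = 259L,
                       chrom_len_cM = 100, chrom_len_bp = 65e6,
                       marker_map = NULL, chrom_lengths = NULL,
                       n_backcrosses = 3L, n_selfings = 10L,
                       make_hybrids = FALSE, missing_rate = 0,
                       planted_qtls = NULL, n_replicates = 3L,
                       noise_sd = 1, baseline = 10,
                       control_line_id = "TA209", seed) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory for reproducibility")
  stopifnot(n_backcrosses >= 0, n_selfings >= 0, missing_rate >= 0, missing_rate < 1)
  structure(list(
    n_lines = as.integer(n_lines), n_chrom = as.integer(n_chrom),
    markers_per_chrom = as.integer(markers_per_chrom),
    chrom_len_cM = chrom_len_cM, chrom_len_bp = chrom_len_bp,
    marker_map = marker_map, chrom_lengths = chrom_lengths,
    n_backcrosses = as.integer(n_backcrosses), n_selfings = as.integer(n_selfings),
    make_hybrids = make_hybrids, missing_rate = missing_rate,
    planted_qtls = planted_qtls, n_replicates = as.integer(n_replicates),
    noise_sd = noise_sd, baseline = baseline,
    control_line_id = control_line_id, seed = as.integer(seed)
  ), class = "sim_config")
}

# a haplotype is list(ends, alleles): segment i covers
# (ends[i-1], ends[i]] on the cM axis; alleles are 0 (recurrent) or
# 1 (donor); last end equals the chromosome length.
hap_const <- function(len_cM, allele) list(ends = len_cM, alleles = allele)

#' Simulate one meiotic gamete
#'
#' Crossovers per chromosome are Poisson with mean `len_cM / 100`
#' (Haldane model, no interference), breakpoints uniform on the cM
#' axis, and the starting phase is a fair coin.  Two identical
#' haplotypes yield the parental haplotype regardless of crossovers.
#'
#' @param h1,h2 Haplotypes: lists with numeric `ends` (segment end
#'   positions in cM, last = chromosome length) and integer `alleles`
#'   (0 recurrent / 1 donor).
#' @param len_cM Chromosome length in cM.
#' @return A haplotype in the same representation.
#' @export
simulate_gamete <- function(h1, h2, len_cM) {
  if (identical(h1, h2)) return(h1)
  k <- rpois(1L, len_cM / 100)
  phase <- sample.int(2L, 1L)
  if (k == 0L) return(if (phase == 1L) h1 else h2)
  cuts <- sort(runif(k, 0, len_cM))
  haps <- list(h1, h2)
  bounds <- c(cuts, len_cM)
  ends <- numeric(0); alleles <- integer(0)
  a <- 0
  cur <- phase
  for (b in bounds) {
    if (b > a) {
      h <- haps[[cur]]
      i1 <- findInterval(a, h$ends, left.open = TRUE) + 1L
      i2 <- findInterval(b, h$ends, left.open = TRUE) + 1L
      seg_ends <- c(h$ends[i1:i2][h$ends[i1:i2] < b], b)
      ends <- c(ends, seg_ends)
      alleles <- c(alleles, h$alleles[i1:i2][seq_along(seg_ends)])
      a <- b
    }
    cur <- 3L - cur
  }
  # compress runs of equal alleles
  r <- rle(alleles)
  list(ends = ends[cumsum(r$lengths)], alleles = r$values)
}

# self or cross: an individual is a list of per-chromosome
# list(h1, h2) haplotype pairs
gamete_individual <- function(ind, lens) {
  lapply(seq_along(ind), function(ci) {
    simulate_gamete(ind[[ci]]$h1, ind[[ci]]$h2, lens[ci])
  })
}

auto_map <- function(config) {
  chroms <- sprintf("chr%02d", seq_len(config$n_chrom))
  m <- config$markers_per_chrom
  mm <- dplyr::bind_rows(lapply(chroms, function(ch) {
    pos <- round(seq_len(m) * config$chrom_len_bp / (m + 1))
    tibble::tibble(marker_id = sprintf("%s_m%04d", ch, seq_len(m)),
                   chrom = ch, pos_bp = as.integer(pos))
  }))
  cl <- tibble::tibble(chrom = chroms,
                       length_bp = as.integer(config$chrom_len_bp))
  list(marker_map = mm, chrom_lengths = cl,
       len_cM = setNames(rep(config$chrom_len_cM, length(chroms)), chroms))
}

#' Forward-simulate a BIL population
#'
#' Runs the breeding scheme per line: F1 (donor x recurrent), then
#' `n_backcrosses` crosses to the recurrent parent, then `n_selfings`
#' generations of self-pollination carrying one offspring forward
#' (single-seed descent).  Genotypes are read at the marker positions;
#' the exact donor segments of every line (the simulation truth) are
#' recorded in cM and bp.
#'
#' @param config A [sim_config()].
#' @return A list of class `bil_sim`: `genotypes`, `marker_map`,
#'   `chrom_lengths`, `truth` (tibble `line_id`, `chrom`, `start_cM`,
#'   `end_cM`, `start_bp`, `end_bp`, `zygosity`), `config`, plus
#'   `hybrids` and `truth_hybrid` when `config$make_hybrids`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(config$marker_map)) {
    g <- auto_map(config)
    marker_map <- g$marker_map; chrom_lengths <- g$chrom_lengths
    len_cM <- g$len_cM
  } else {
    marker_map <- validate_marker_map(config$marker_map)
    chrom_lengths <- config$chrom_lengths
    len_cM <- setNames(rep(config$chrom_len_cM, nrow(chrom_lengths)),
                       chrom_lengths$chrom)
  }
  chroms <- chrom_lengths$chrom
  len_bp <- setNames(chrom_lengths$length_bp, chroms)
  marker_cM <- lapply(chroms, function(ch) {
    p <- marker_map$pos_bp[marker_map$chrom == ch]
    p / len_bp[[ch]] * len_cM[[ch]]
  })
  names(marker_cM) <- chroms

  recurrent <- lapply(chroms, function(ch) {
    list(h1 = hap_const(len_cM[[ch]], 0L), h2 = hap_const(len_cM[[ch]], 0L))
  })
  names(recurrent) <- chroms
  lens <- unname(len_cM[chroms])

  line_ids <- sprintf("BIL%03d", seq_len(config$n_lines))
  finals <- vector("list", config$n_lines)
  hybrids <- if (config$make_hybrids) vector("list", config$n_lines) else NULL
  for (li in seq_len(config$n_lines)) {
    ind <- lapply(chroms, function(ch) {
      list(h1 = hap_const(len_cM[[ch]], 1L), h2 = hap_const(len_cM[[ch]], 0L))
    })
    for (bc in seq_len(config$n_backcrosses)) {
      g <- gamete_individual(ind, lens)
      ind <- lapply(seq_along(chroms), function(ci) {
        list(h1 = g[[ci]], h2 = recurrent[[ci]]$h1)
      })
    }
    for (s in seq_len(config$n_selfings)) {
      g1 <- gamete_individual(ind, lens)
      g2 <- gamete_individual(ind, lens)
      ind <- lapply(seq_along(chroms), function(ci) list(h1 = g1[[ci]], h2 = g2[[ci]]))
    }
    finals[[li]] <- ind
    if (config$make_hybrids) {
      g <- gamete_individual(ind, lens)
      hybrids[[li]] <- lapply(seq_along(chroms), function(ci) {
        list(h1 = g[[ci]], h2 = recurrent[[ci]]$h1)
      })
    }
  }

  emit <- function(inds, ids) {
    calls <- lapply(seq_along(inds), function(li) {
      unlist(lapply(seq_along(chroms), function(ci) {
        cm <- marker_cM[[chroms[ci]]]
        hp <- inds[[li]][[ci]]
        a1 <- hp$h1$alleles[findInterval(cm, hp$h1$ends, left.open = TRUE) + 1L]
        a2 <- hp$h2$alleles[findInterval(cm, hp$h2$ends, left.open = TRUE) + 1L]
        c("A", "H", "B")[a1 + a2 + 1L]
      }), use.names = FALSE)
    })
    m <- do.call(rbind, calls)
    if (config$missing_rate > 0) {
      u <- runif(length(m)) < config$missing_rate
      m[u] <- "U"
    }
    colnames(m) <- marker_map$marker_id
    dplyr::bind_cols(tibble::tibble(line_id = ids),
                     tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE)))
  }
  truth_of <- function(inds, ids) {
    rows <- list()
    for (li in seq_along(inds)) {
      for (ci in seq_along(chroms)) {
        hp <- inds[[li]][[ci]]
        ends <- sort(unique(c(hp$h1$ends, hp$h2$ends)))
        starts <- c(0, head(ends, -1))
        mid <- (starts + ends) / 2
        d <- hp$h1$alleles[findInterval(mid, hp$h1$ends, left.open = TRUE) + 1L] +
             hp$h2$alleles[findInterval(mid, hp$h2$ends, left.open = TRUE) + 1L]
        r <- rle(d)
        e2 <- ends[cumsum(r$lengths)]
        s2 <- c(0, head(e2, -1))
        keep <- r$values > 0
        if (!any(keep)) next
        lc <- len_cM[[chroms[ci]]]; lb <- len_bp[[chroms[ci]]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          line_id = ids[li], chrom = chroms[ci],
          start_cM = s2[keep], end_cM = e2[keep],
          start_bp = pmax(1L, as.integer(floor(s2[keep] / lc * lb)) + 1L),
          end_bp = pmin(as.integer(lb), as.integer(ceiling(e2[keep] / lc * lb))),
          zygosity = ifelse(r$values[keep] == 2, "homozygous", "heterozygous"))
      }
    }
    if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
      line_id = character(), chrom = character(), start_cM = numeric(),
      end_cM = numeric(), start_bp = integer(), end_bp = integer(),
      zygosity = character())
  }

  out <- list(genotypes = emit(finals, line_ids),
              marker_map = marker_map, chrom_lengths = chrom_lengths,
              truth = truth_of(finals, line_ids), config = config)
  if (config$make_hybrids) {
    out$hybrids <- emit(hybrids, line_ids)
    out$truth_hybrid <- truth_of(hybrids, line_ids)
  }
  class(out) <- "bil_sim"
  out
}

#' Per-line donor and heterozygous genome fractions from the truth
#'
#' Computed on the cM axis from the exact simulated segments: donor
#' fraction is allele dosage (a heterozygous segment counts half), the
#' heterozygous fraction is the genome share in heterozygous state.
#'
#' @param sim A `bil_sim` object.
#' @param truth Truth tibble to summarise (defaults to `sim$truth`;
#'   pass `sim$truth_hybrid` for the hybrid set).
#' @return Tibble: `line_id`, `donor_fraction`, `het_fraction` (one
#'   row per line, zero-segment lines included).
#' @export
truth_genome_fractions <- function(sim, truth = sim$truth) {
  total_cM <- sum(rep(sim$config$chrom_len_cM, nrow(sim$chrom_lengths)))
  ids <- sim$genotypes$line_id
  if (!nrow(truth)) {
    return(tibble::tibble(line_id = ids, donor_fraction = 0, het_fraction = 0))
  }
  per <- dplyr::summarise(dplyr::group_by(truth, .data$line_id),
    donor_cM = sum((.data$end_cM - .data$start_cM) *
                     ifelse(.data$zygosity == "homozygous", 1, 0.5)),
    het_cM = sum((.data$end_cM - .data$start_cM) *
                   (.data$zygosity == "heterozygous")),
    .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(line_id = ids), per, by = "line_id")
  tibble::tibble(line_id = out$line_id,
                 donor_fraction = ifelse(is.na(out$donor_cM), 0, out$donor_cM) / total_cM,
                 het_fraction = ifelse(is.na(out$het_cM), 0, out$het_cM) / total_cM)
}

#' Attach simulated metabolite phenotypes with planted QTLs
#'
#' Each replicate value is `baseline + sum(effect x dosage) +
#' dominance x [heterozygous] + N(0, noise_sd)`, where dosage is the
#' line's true donor-allele dosage (0, 0.5, 1) at the QTL marker,
#' taken from the simulation truth.  The control (recurrent parent)
#' line carries no donor allele and so receives baseline plus noise.
#'
#' @param sim A `bil_sim` object.
#' @param qtls Planted-QTL tibble (`trait_id`, `marker_id`, `effect`,
#'   optional `dominance`); defaults to `config$planted_qtls`.
#' @param null_traits Names of additional traits simulated with no
#'   QTL (pure replicate noise around baseline).
#' @param hybrid Use the hybrid set's truth instead of the inbred
#'   lines'.
#' @return Long phenotype tibble (`line_id`, `trait_id`, `replicate`,
#'   `value`) including the control line.
#' @export
simulate_phenotypes <- function(sim, qtls = NULL, null_traits = character(0),
                                hybrid = FALSE) {
  config <- sim$config
  qtls <- qtls %||% config$planted_qtls
  if (is.null(qtls)) {
    qtls <- tibble::tibble(trait_id = character(), marker_id = character(),
                           effect = numeric())
  }
  if (!"dominance" %in% names(qtls)) qtls$dominance <- 0
  unknown <- setdiff(qtls$marker_id, sim$marker_map$marker_id)
  if (length(unknown)) {
    abort(paste0("planted QTL at unknown marker: ", paste(unknown, collapse = ", ")))
  }
  truth <- if (hybrid) sim$truth_hybrid else sim$truth
  geno <- if (hybrid) sim$hybrids else sim$genotypes
  ids <- geno$line_id
  len_bp <- setNames(sim$chrom_lengths$length_bp, sim$chrom_lengths$chrom)

  dosage_at <- function(marker_id) {
    mrow <- sim$marker_map[sim$marker_map$marker_id == marker_id, ]
    cm <- mrow$pos_bp / len_bp[[mrow$chrom]] * config$chrom_len_cM
    d <- setNames(rep(0, length(ids)), ids)
    tr <- truth[truth$chrom == mrow$chrom &
                  truth$start_cM < cm & truth$end_cM >= cm, ]
    if (nrow(tr)) {
      w <- ifelse(tr$zygosity == "homozygous", 1, 0.5)
      d[tr$line_id] <- w
    }
    d
  }

  traits <- unique(c(qtls$trait_id, null_traits))
  all_ids <- c(ids, config$control_line_id)
  rows <- lapply(traits, function(tr) {
    qs <- qtls[qtls$trait_id == tr, , drop = FALSE]
    genetic <- setNames(rep(0, length(all_ids)), all_ids)
    for (k in seq_len(nrow(qs))) {
      d <- dosage_at(qs$marker_id[k])
      genetic[names(d)] <- genetic[names(d)] + qs$effect[k] * d +
        qs$dominance[k] * (d == 0.5)
    }
    tidyr::expand_grid(line_id = all_ids, replicate = seq_len(config$n_replicates)) |>
      dplyr::mutate(trait_id = tr,
                    value = config$baseline + genetic[.data$line_id] +
                      rnorm(dplyr::n(), 0, config$noise_sd))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "line_id", "trait_id", "replicate", "value")
}

#' Simulate a complete BIL study (genotypes + phenotypes)
#'
#' Convenience wrapper: [simulate_population()] followed by
#' [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @param null_traits Passed to [simulate_phenotypes()].
#' @return The `bil_sim` list with a `phenotypes` element added.
#' @export
simulate_bil_study <- function(config, null_traits = character(0)) {
  sim <- simulate_population(config)
  sim$phenotypes <- simulate_phenotypes(sim, null_traits = null_traits)
  sim
}
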