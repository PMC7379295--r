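#' Run the full BIL analysis pipeline
#'
#' Executes the stages in order — (optional) simulation, introgression
#' calling, bin building, genetic-map construction, metabolite
#' normalisation, QTL scanning per experiment, cross-experiment
#' conservation — writing TSV tables, a `report.json` with the
#' headline statistics, and a `manifest.json` (config snapshot, input
#' checksums, seed, package version, per-stage wall times) to
#' `out_dir`.  `report.json` and all TSV outputs are deterministic for
#' a fixed seed; timestamps live only in the manifest.
#'
#' @param config A named list (or path to a YAML file) with either a
#'   `simulate` block (arguments for [sim_config()], plus optional
#'   `planted_qtls` and `null_traits`) or an `inputs` block
#'   (`genotypes`, `marker_map`, `chrom_lengths`, and `phenotypes` — a
#'   named list of experiment-id -> file).  Optional blocks:
#'   `control_line`, `scan` (`method` `"anova"`/`"hk"`,
#'   `threshold_mode`, `alpha`, `n_permutations`, `lod_drop`,
#'   `step_cM`), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `report` (as written) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  seed <- config$seed %||% 1L
  checksums <- list()

  if (!is.null(config$simulate)) {
    sc_args <- config$simulate
    nulls <- sc_args$null_traits %||% character(0)
    sc_args$null_traits <- NULL
    if (!is.null(sc_args$planted_qtls)) {
      sc_args$planted_qtls <- dplyr::bind_rows(lapply(sc_args$planted_qtls, tibble::as_tibble))
    }
    sc_args$seed <- sc_args$seed %||% seed
    sc <- do.call(sim_config, sc_args)
    sim <- simulate_bil_study(sc, null_traits = nulls)
    geno <- sim$genotypes; marker_map <- sim$marker_map
    chrom_lengths <- sim$chrom_lengths
    phenos <- list(sim = sim$phenotypes)
    control_line <- config$control_line %||% sc$control_line_id
    write_genotypes(geno, file.path(out_dir, "genotypes.tsv"))
    readr::write_tsv(marker_map, file.path(out_dir, "marker_map.tsv"), progress = FALSE)
    readr::write_tsv(chrom_lengths, file.path(out_dir, "chrom_lengths.tsv"), progress = FALSE)
    write_phenotypes(sim$phenotypes, file.path(out_dir, "phenotypes_sim.tsv"))
    inform(paste0("simulate: ", nrow(geno), " lines x ", nrow(marker_map), " markers"))
    tick("simulate")
  } else if (!is.null(config$inputs)) {
    ip <- config$inputs
    marker_map <- read_marker_map(ip$marker_map)
    chrom_lengths <- read_chrom_lengths(ip$chrom_lengths)
    geno <- read_genotypes(ip$genotypes, marker_map,
                           recode = unlist(ip$genotype_recode))
    ph_files <- ip$phenotypes %||% list()
    phenos <- lapply(ph_files, read_phenotypes)
    if (is.null(names(phenos)) || any(names(phenos) == "")) {
      names(phenos) <- paste0("exp", seq_along(phenos))
    }
    control_line <- config$control_line
    checksums <- as.list(tools::md5sum(unlist(c(ip$genotypes, ip$marker_map,
                                                ip$chrom_lengths, ph_files))))
    inform(paste0("read: ", nrow(geno), " lines x ", nrow(marker_map), " markers, ",
                  length(phenos), " phenotype table(s)"))
    tick("read")
  } else {
    abort("config needs a 'simulate' or an 'inputs' block")
  }

  segments <- call_introgressions(geno, marker_map, chrom_lengths)
  pop <- summarize_population(segments, nrow(geno), chrom_lengths)
  readr::write_tsv(segments, file.path(out_dir, "segments.tsv"), progress = FALSE)
  inform(paste0("call-introgressions: ", nrow(segments), " segments in ",
                pop$n_lines_with_segment, "/", pop$n_lines_total, " lines"))
  tick("call_introgressions")

  bins <- build_bins(geno, marker_map, chrom_lengths)
  bsum <- bin_summary(bins)
  bins_flat <- dplyr::mutate(tibble::as_tibble(unclass(bins)),
                             marker_ids = vapply(.data$marker_ids, paste,
                                                 character(1), collapse = ","))
  readr::write_tsv(bins_flat, file.path(out_dir, "bins.tsv"), progress = FALSE)
  write_genotypes(bin_genotypes(bins), file.path(out_dir, "bin_genotypes.tsv"))
  inform(paste0("build-bins: ", bsum$n_bins, " bins"))
  tick("build_bins")

  gmap <- build_map(bins)
  msum <- glance(gmap)
  readr::write_tsv(tibble::as_tibble(gmap), file.path(out_dir, "map.tsv"),
                   progress = FALSE)
  inform(paste0("build-map: ", round(msum$total_length_cM, 1), " cM in ",
                msum$n_groups, " linkage groups"))
  tick("build_map")

  fold <- NULL
  for (exp_id in names(phenos)) {
    if (!is.null(control_line) && control_line %in% phenos[[exp_id]]$line_id) {
      fc <- normalize_to_control(phenos[[exp_id]], control_line)
      readr::write_tsv(tibble::as_tibble(unclass_fc(fc)),
                       file.path(out_dir, paste0("foldchanges_", exp_id, ".tsv")),
                       progress = FALSE)
      fr <- fold_range(fc)
      fold[[exp_id]] <- list(min_fold = fr$min_fold, max_fold = fr$max_fold)
    }
  }
  tick("normalize")

  scan_cfg <- config$scan %||% list()
  cfg <- scan_config(
    lod_drop = scan_cfg$lod_drop %||% 1,
    threshold_mode = scan_cfg$threshold_mode %||% "permutation",
    n_permutations = scan_cfg$n_permutations %||% 1000L,
    alpha = scan_cfg$alpha %||% 0.05,
    seed = seed)
  method <- scan_cfg$method %||% "anova"
  scans <- list()
  for (exp_id in names(phenos)) {
    scans[[exp_id]] <- if (method == "hk") {
      hk_scan(phenos[[exp_id]], bins, gmap, cfg, experiment_id = exp_id,
              step_cM = scan_cfg$step_cM %||% 1)
    } else {
      anova_scan(phenos[[exp_id]], bins, cfg, experiment_id = exp_id)
    }
    readr::write_tsv(tidy(scans[[exp_id]]),
                     file.path(out_dir, paste0("qtl_", exp_id, ".tsv")),
                     progress = FALSE)
    inform(paste0("scan[", exp_id, "]: ", nrow(scans[[exp_id]]), " QTLs (",
                  method, ")"))
  }
  tick("scan")

  conserved <- NULL
  if (length(scans) >= 2L) {
    conserved <- conserved_qtls(scans)
    readr::write_tsv(conserved, file.path(out_dir, "conserved.tsv"), progress = FALSE)
    inform(paste0("conserved: ", sum(conserved$conserved), " conserved clusters"))
  }
  tick("conserved")

  report <- list(
    population = as.list(pop),
    bins = as.list(bsum),
    map = as.list(msum),
    fold_range = fold,
    qtl = lapply(scans, function(s) list(n_qtls = nrow(s),
                                         n_traits_scanned = glance(s)$n_traits)),
    conserved = if (!is.null(conserved)) list(
      n_clusters = nrow(conserved),
      n_conserved = sum(conserved$conserved)) else NULL
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  manifest <- list(
    package = "bilqtl",
    version = as.character(utils::packageVersion("bilqtl")),
    seed = seed,
    config = config,
    input_checksums = checksums,
    stage_seconds = timings,
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(report = report, out_dir = out_dir))
}

unclass_fc <- function(fc) {
  attr(fc, "control_line_id") <- NULL
  class(fc) <- c("tbl_df", "tbl", "data.frame")
  fc
}
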