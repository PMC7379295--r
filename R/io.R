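#' Read a marker map
#'
#' A marker map anchors every SNP to a chromosome and a physical
#' position; it is the coordinate backbone for segment calling, bin
#' construction and QTL reporting.
#'
#' @param path Tab-separated file with columns `marker_id`, `chrom`,
#'   `pos_bp` (1-based base pairs).
#' @return A tibble with columns `marker_id`, `chrom`, `pos_bp`, sorted
#'   by chromosome (order of first appearance) and position.
#' @export
read_marker_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    chrom = readr::col_character(),
    pos_bp = readr::col_double()
  ), progress = FALSE)
  validate_marker_map(tibble::as_tibble(df))
}

validate_marker_map <- function(map) {
  req <- c("marker_id", "chrom", "pos_bp")
  if (!all(req %in% names(map))) {
    abort(paste0("marker map must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(map$marker_id)) {
    abort("marker map: duplicated marker_id")
  }
  if (any(!is.finite(map$pos_bp)) || any(map$pos_bp < 1)) {
    abort("marker map: pos_bp must be finite and >= 1")
  }
  map$pos_bp <- as.integer(round(map$pos_bp))
  chrom_order <- unique(map$chrom)
  map <- map[order(match(map$chrom, chrom_order), map$pos_bp), , drop = FALSE]
  dup <- unlist(tapply(map$pos_bp, factor(map$chrom, levels = chrom_order),
                       function(p) duplicated(p)), use.names = FALSE)
  if (any(dup)) {
    abort("marker map: marker positions must be strictly increasing within a chromosome")
  }
  tibble::as_tibble(map[, req])
}

#' Read a chromosome-length table
#'
#' @param path Tab-separated file with columns `chrom`, `length_bp`.
#' @return A tibble with columns `chrom`, `length_bp`.
#' @export
read_chrom_lengths <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    length_bp = readr::col_double()
  ), progress = FALSE)
  df$length_bp <- as.integer(round(df$length_bp))
  if (anyDuplicated(df$chrom)) abort("chromosome table: duplicated chrom")
  if (any(df$length_bp < 1)) abort("chromosome table: length_bp must be >= 1")
  tibble::as_tibble(df)
}

validate_chrom_lengths <- function(map, chrom_lengths) {
  missing_chrom <- setdiff(map$chrom, chrom_lengths$chrom)
  if (length(missing_chrom)) {
    abort(paste0("chromosomes absent from the chromosome table: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  maxpos <- tapply(map$pos_bp, map$chrom, max)
  len <- setNames(chrom_lengths$length_bp, chrom_lengths$chrom)
  bad <- names(maxpos)[maxpos > len[names(maxpos)]]
  if (length(bad)) {
    abort(paste0("marker position exceeds chromosome length on: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a genotype matrix
#'
#' Reads a lines-by-markers table of categorical genotype calls and
#' validates it against a marker map.  The canonical alphabet is
#' `A` (homozygous recurrent parent), `B` (homozygous donor),
#' `H` (heterozygous) and `U` (missing); source files using a different
#' encoding are translated through `recode`.
#'
#' @param path Tab-separated file: first column line ids, remaining
#'   columns one per marker (header = marker ids).
#' @param marker_map Marker map tibble (see [read_marker_map()]); the
#'   file's marker set must equal the map's, and columns are reordered
#'   to map order.
#' @param recode Optional named character vector translating source
#'   symbols to the canonical alphabet, e.g.
#'   `c("0" = "A", "2" = "B", "1" = "H", "-" = "U")`.
#' @return A genotype tibble: column `line_id`, then one character
#'   column per marker in map order.
#' @export
read_genotypes <- function(path, marker_map, recode = NULL) {
  marker_map <- validate_marker_map(marker_map)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  names(df)[1] <- "line_id"
  if (!is.null(recode)) {
    df[-1] <- lapply(df[-1], function(x) {
      hit <- x %in% names(recode)
      x[hit] <- unname(recode[x[hit]])
      x
    })
  }
  validate_genotypes(tibble::as_tibble(df), marker_map)
}

validate_genotypes <- function(geno, marker_map) {
  if (names(geno)[1] != "line_id") names(geno)[1] <- "line_id"
  if (anyDuplicated(geno$line_id)) abort("genotypes: duplicated line_id")
  file_markers <- names(geno)[-1]
  unknown <- setdiff(file_markers, marker_map$marker_id)
  if (length(unknown)) {
    abort(paste0("genotypes: markers absent from the marker map: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  absent <- setdiff(marker_map$marker_id, file_markers)
  if (length(absent)) {
    abort(paste0("genotypes: markers in the map but not in the file: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  geno <- geno[, c("line_id", marker_map$marker_id)]
  vals <- unique(unlist(lapply(geno[-1], unique), use.names = FALSE))
  bad <- setdiff(vals, GENO_CODES)
  if (length(bad)) {
    abort(paste0("genotypes: symbols outside the {A,B,H,U} alphabet ",
                 "(supply a recoding map): ", paste(head(bad, 10), collapse = ", ")))
  }
  tibble::as_tibble(geno)
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()] for the canonical dialect; a written
#' file read back and re-written is byte-identical.
#'
#' @param geno Genotype tibble.
#' @param path Output TSV path.
#' @export
write_genotypes <- function(geno, path) {
  readr::write_tsv(geno, path, progress = FALSE)
  invisible(path)
}

#' Read a metabolite phenotype table
#'
#' Phenotypes are nonnegative relative responses (e.g. GC-MS peak
#' responses) measured per line, trait and biological replicate.
#' Missing values (`NA` cells) are dropped, not imputed; downstream
#' means use the available replicates.
#'
#' @param path Tab-separated file.
#' @param format `"long"` (columns `line_id`, `trait_id`, optionally
#'   `replicate`, `value`) or `"wide"` (first column line ids, one
#'   column per trait; repeated line rows are treated as replicates).
#' @return A long tibble with columns `line_id`, `trait_id`,
#'   `replicate`, `value`.  A replicate index is assigned when absent.
#' @export
read_phenotypes <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (format == "wide") {
    names(df)[1] <- "line_id"
    df <- tidyr::pivot_longer(df, -"line_id",
                              names_to = "trait_id", values_to = "value")
  } else {
    if (!all(c("line_id", "trait_id", "value") %in% names(df))) {
      abort("long phenotype table needs columns line_id, trait_id, value")
    }
  }
  suppressWarnings(num <- as.numeric(df$value))
  bad <- !is.na(df$value) & df$value != "NA" & is.na(num)
  if (any(bad)) {
    abort(paste0("phenotypes: non-numeric value(s): ",
                 paste(head(unique(df$value[bad]), 5), collapse = ", ")))
  }
  df$value <- num
  df <- df[!is.na(df$value), , drop = FALSE]
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    abort("phenotypes: values must be finite and nonnegative")
  }
  if (!"replicate" %in% names(df)) {
    df <- dplyr::mutate(dplyr::group_by(df, .data$line_id, .data$trait_id),
                        replicate = dplyr::row_number())
    df <- dplyr::ungroup(df)
  } else {
    df$replicate <- as.integer(df$replicate)
  }
  dplyr::select(tibble::as_tibble(df), "line_id", "trait_id", "replicate", "value")
}

#' Write a phenotype table (long canonical dialect)
#'
#' @param phenotypes Long phenotype tibble.
#' @param path Output TSV path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path, progress = FALSE)
  invisible(path)
}

# lines x markers character matrix (rownames = line ids)
geno_matrix <- function(geno) {
  m <- as.matrix(geno[, -1, drop = FALSE])
  rownames(m) <- geno$line_id
  m
}

# donor-informative collapse: A -> 0, B/H -> 1, U -> NA.
# H carries a wild allele, so for segment/linkage purposes it is
# donor-state; zygosity is tracked separately.
donor_state <- function(calls) {
  out <- rep(NA_real_, length(calls))
  out[calls == "A"] <- 0
  out[calls %in% c("B", "H")] <- 1
  dim(out) <- dim(calls)
  dimnames(out) <- dimnames(calls)
  out
}
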