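#' Normalise metabolite responses to a control line
#'
#' Computes per-trait fold changes of line means relative to the mean
#' response of a control line (the recurrent parent).  Zero raw
#' responses are treated as missing (GC-MS non-detects), not as
#' literal zeros, so downstream log transforms stay defined; traits
#' whose control mean is zero or undefined are dropped with a message.
#'
#' @param phenotypes Long phenotype tibble.
#' @param control_line_id Line id of the control (e.g. the recurrent
#'   parent cultivar).
#' @return A long tibble of class `bil_foldchange` with columns
#'   `line_id`, `trait_id`, `fold_change` (linear, positive).  The
#'   control line's own fold change is 1 by construction.  The control
#'   id is attached as an attribute.
#' @export
normalize_to_control <- function(phenotypes, control_line_id) {
  if (!control_line_id %in% phenotypes$line_id) {
    abort(paste0("control line not present: ", control_line_id))
  }
  ph <- phenotypes
  ph$value[ph$value == 0] <- NA_real_
  ph <- ph[!is.na(ph$value), , drop = FALSE]
  means <- dplyr::summarise(dplyr::group_by(ph, .data$line_id, .data$trait_id),
                            value = mean(.data$value), .groups = "drop")
  ctrl <- means[means$line_id == control_line_id, c("trait_id", "value")]
  names(ctrl)[2] <- "control_mean"
  bad <- ctrl$trait_id[!is.finite(ctrl$control_mean) | ctrl$control_mean <= 0]
  traits_all <- unique(means$trait_id)
  no_ctrl <- setdiff(traits_all, ctrl$trait_id)
  drop <- union(bad, no_ctrl)
  if (length(drop)) {
    inform(paste0("dropping trait(s) without a usable control mean: ",
                  paste(drop, collapse = ", ")))
  }
  fc <- dplyr::inner_join(means, ctrl[!ctrl$trait_id %in% drop, ], by = "trait_id")
  out <- tibble::tibble(line_id = fc$line_id, trait_id = fc$trait_id,
                        fold_change = fc$value / fc$control_mean)
  attr(out, "control_line_id") <- control_line_id
  class(out) <- c("bil_foldchange", class(out))
  out
}

#' Log2 heat-map matrix of fold changes
#'
#' @param foldchanges A `bil_foldchange` tibble (linear scale).
#' @return A wide tibble: `line_id` rows (input order preserved per
#'   first appearance), one numeric column per trait (sorted), values
#'   `log2(fold change)`.  Nonpositive fold changes are an error —
#'   they must be dropped upstream.
#' @export
heatmap_matrix <- function(foldchanges) {
  if (any(foldchanges$fold_change <= 0, na.rm = TRUE)) {
    abort("nonpositive fold change; drop zero responses upstream")
  }
  lg <- dplyr::mutate(foldchanges, log2_fc = log2(.data$fold_change))
  wide <- tidyr::pivot_wider(lg[, c("line_id", "trait_id", "log2_fc")],
                             names_from = "trait_id", values_from = "log2_fc")
  wide <- wide[, c("line_id", sort(names(wide)[-1]))]
  wide[order(match(wide$line_id, unique(foldchanges$line_id))), ]
}

#' Global fold-change range of a population
#'
#' Minimum and maximum fold change over all (line, trait) cells,
#' excluding the control line itself.
#'
#' @param foldchanges A `bil_foldchange` tibble.
#' @return One-row tibble: `min_fold`, `max_fold`.
#' @export
fold_range <- function(foldchanges) {
  ctrl <- attr(foldchanges, "control_line_id")
  x <- if (is.null(ctrl)) foldchanges$fold_change else
    foldchanges$fold_change[foldchanges$line_id != ctrl]
  x <- x[is.finite(x)]
  if (!length(x)) abort("empty fold-change matrix")
  tibble::tibble(min_fold = min(x), max_fold = max(x))
}
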