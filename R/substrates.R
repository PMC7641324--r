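# Substrate geometry: end-labeled linear duplexes, with or without a Chi site.

#' Describe one 5'-end-labeled linear duplex substrate
#'
#' Coordinates are 0-based nucleotide distances measured from the enzyme
#' entry end; the radiolabeled 5' end is always the end distal to entry, so a
#' cut at distance `p` from entry leaves a labeled fragment of
#' `length_nt - p` nucleotides.
#'
#' @param name Substrate label.
#' @param length_nt Total duplex length, nt.
#' @param entry_end Which end RecBCD enters, `"left"` or `"right"`. Chi is
#'   only active for the orientation the substrate was designed for; the
#'   packaged substrates use right entry.
#' @param chi_cut_from_label Distance (nt) from the labeled end to the
#'   nominal Chi-dependent cut, or `NA` for a Chi-free substrate.
#' @param chi_status Optional label, `"chi_plus"` or `"chi_zero"`; inferred
#'   from `chi_cut_from_label` when missing.
#' @return A one-row tibble of class `substrate_spec`.
#' @export
substrate_spec <- function(name, length_nt, entry_end = c("right", "left"),
                           chi_cut_from_label = NA_real_,
                           chi_status = NULL) {
  entry_end <- match.arg(entry_end)
  if (!is.numeric(length_nt) || length_nt <= 0) {
    rlang::abort("`length_nt` must be positive.",
                 class = "chirace_invalid_parameter")
  }
  if (!is.na(chi_cut_from_label) &&
      (chi_cut_from_label <= 0 || chi_cut_from_label >= length_nt)) {
    rlang::abort("`chi_cut_from_label` must lie strictly inside the substrate.",
                 class = "chirace_invalid_parameter")
  }
  if (is.null(chi_status)) {
    chi_status <- if (is.na(chi_cut_from_label)) "chi_zero" else "chi_plus"
  }
  out <- tibble::tibble(
    name = as.character(name), length_nt = as.numeric(length_nt),
    entry_end = entry_end, chi_status = chi_status,
    chi_cut_from_label = as.numeric(chi_cut_from_label)
  )
  class(out) <- c("substrate_spec", class(out))
  out
}

#' The three packaged substrate lengths, with and without Chi
#'
#' The standard cutting assay uses singly end-labeled duplexes of ~4350,
#' 2270 and 1340 bp, each in a Chi-plus and a Chi-free version. In the
#' Chi-plus versions the Chi-dependent cut lies 970 nt from the labeled end,
#' and the enzyme enters from the end (here "right") for which Chi is in its
#' active orientation.
#'
#' @return A six-row `substrate_spec` tibble (three lengths x two Chi states).
#' @examples
#' make_default_substrates()
#' @export
make_default_substrates <- function() {
  lens <- c(4350, 2270, 1340)
  rows <- purrr::map(lens, function(L) {
    dplyr::bind_rows(
      substrate_spec(sprintf("chi_plus_%d", L), L, "right",
                     chi_cut_from_label = 970),
      substrate_spec(sprintf("chi_zero_%d", L), L, "right")
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("substrate_spec", class(tibble::tibble()))
  out
}

# Internal: Chi cut distance from the entry end (NA when no Chi).
chi_cut_from_entry <- function(sub) {
  ifelse(is.na(sub$chi_cut_from_label), NA_real_,
         sub$length_nt - sub$chi_cut_from_label)
}
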