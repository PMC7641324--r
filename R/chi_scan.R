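# Orientation-aware scanning for the Chi hotspot 8-mer.

CHI_MOTIF <- "GCTGGTGG"

#' Scan a DNA sequence for correctly oriented Chi sites
#'
#' The Chi hotspot is the 8-mer 5'-GCTGGTGG-3'. RecBCD recognizes it only
#' when approached from the correct direction: entering from the right end
#' (as conventionally drawn, top strand 5'->3' left to right) the enzyme
#' reads Chi on the top strand; entering from the left it reads the bottom
#' strand, i.e. the reverse complement `CCACCAGC` on the top strand.
#'
#' Each hit is reported as a cut distance from the entry end: the distance
#' from entry to the motif base nearest the entry, minus `chi_offset_nt`
#' (the nuclease cuts a few nucleotides 3' of the Chi 8-mer). A hit closer
#' to the entry than the offset is clamped to a cut distance of 0.
#'
#' @param sequence Top strand, 5'->3', as a character string over A/C/G/T.
#' @param entry_end `"right"` or `"left"` enzyme entry.
#' @param chi_offset_nt Cut offset in nt (default 5, the middle of the
#'   observed 4-6 nt range).
#' @return Numeric vector of cut distances from the entry end, sorted
#'   ascending; empty when no correctly oriented Chi is present.
#' @examples
#' chi_scan("AAAAAGCTGGTGGAAAAAAA", "right")  # one hit, 2 nt from entry
#' chi_scan("GCTGGTGG", "left")               # wrong orientation: empty
#' @export
chi_scan <- function(sequence, entry_end = c("right", "left"),
                     chi_offset_nt = 5) {
  entry_end <- match.arg(entry_end)
  if (!is.character(sequence) || length(sequence) != 1L) {
    rlang::abort("`sequence` must be a single character string.",
                 class = "chirace_parse_error")
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    rlang::abort("`sequence` contains non-ACGT characters.",
                 class = "chirace_parse_error")
  }
  if (nchar(sequence) < nchar(CHI_MOTIF)) {
    rlang::abort("`sequence` is shorter than the Chi 8-mer.",
                 class = "chirace_parse_error")
  }
  L <- nchar(sequence)
  dna <- Biostrings::DNAString(sequence)
  if (entry_end == "right") {
    m <- Biostrings::matchPattern(CHI_MOTIF, dna)
    # motif base nearest a right entry is its last base (1-based `end`)
    dist_entry <- L - BiocGenerics::end(m)
  } else {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(CHI_MOTIF)))
    m <- Biostrings::matchPattern(rc, dna)
    dist_entry <- BiocGenerics::start(m) - 1L
  }
  sort(pmax(0, as.numeric(dist_entry) - chi_offset_nt))
}

#' Scan FASTA records for Chi cut sites
#'
#' Reads a (possibly multi-record) FASTA file and runs [chi_scan()] on each
#' record's top strand.
#'
#' @param path Path to a FASTA file.
#' @inheritParams chi_scan
#' @return A tibble with columns `record`, `entry_end`, `cut_distance_nt`
#'   (zero rows for records without a correctly oriented Chi).
#' @export
scan_chi_fasta <- function(path, entry_end = c("right", "left"),
                           chi_offset_nt = 5) {
  entry_end <- match.arg(entry_end)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) rlang::abort(
      sprintf("Could not parse FASTA file '%s': %s", path, conditionMessage(e)),
      class = "chirace_parse_error")
  )
  purrr::map2_dfr(names(seqs), as.character(seqs), function(nm, s) {
    cuts <- chi_scan(s, entry_end, chi_offset_nt)
    if (length(cuts) == 0) return(tibble::tibble())
    tibble::tibble(record = nm, entry_end = entry_end, cut_distance_nt = cuts)
  })
}
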