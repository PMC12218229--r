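#' Modification specification for scaffold engineering
#'
#' Bundles the tunable parameters of the four modification classes applied
#' to a pri-miRNA: the basal dinucleotide written at offsets -14/-13, the
#' CHC bulge position and identity, the debulge window, the stem-length
#' target, the replacement terminal loop and the unstructured-flank length.
#' Defaults are the determinants of efficient DROSHA/DICER processing:
#' `GU` at -14/-13, a CHC bulge at offset -6, a bulge-free window from
#' -13 to 0, a 35-bp stem (13 basal pairs plus a 22-bp mature duplex) and
#' 10-nt unstructured flanks.
#'
#' The default `loop_sequence` is the 19-nt miR-30a loop region
#' (`CUGUGAAGCCACAGAUGGG`, the segment between the mature miR-30a arms,
#' which carries a short internal helix of its own); the exact boundaries of
#' the loop are an editable choice, not asserted ground truth. The default
#' bulged nucleotide is `A` (H in the C-H-C
#' context may be A, C or U; A keeps the bulge register unambiguous next to
#' the paired C/C context).
#'
#' @param basal_dinucleotide 2-mer written at offsets -14 (first character)
#'   and -13 (second character) on the 5' strand. The motif literature also
#'   writes this element as UG; the orientation is configurable.
#' @param chc_offset Offset of the basal-stem pair 5' of the bulge
#'   (default -6); must lie within `debulge_window`.
#' @param chc_bulge_nt The bulged H nucleotide, one of A, C, U.
#' @param chc_strand Strand carrying the bulge; only the 3' (passenger-side
#'   basal) strand is implemented, matching the bulge-determinant geometry.
#' @param debulge_window Closed offset interval kept free of bulges
#'   (default `c(-13, 0)`).
#' @param stem_len_target Base pairs in the refolded stem (default 35).
#' @param loop_sequence Replacement terminal loop (RNA string).
#' @param flank_unstructured_len Nucleotides kept unpaired beyond the stem
#'   on each side (default 10).
#' @param max_pri_len Scaffold length budget (default 200).
#' @param max_attempts Redesign iterations before giving up (default 50).
#' @param cnnc_window Offset window (nt downstream of the 3p arm end) in
#'   which [screen_candidates()] requires a CNNC motif start (default
#'   `c(16, 21)`).
#' @return A `ModificationSpec` object.
#' @export
modification_spec <- function(basal_dinucleotide = "GU",
                              chc_offset = -6L,
                              chc_bulge_nt = "A",
                              chc_strand = "3p",
                              debulge_window = c(-13L, 0L),
                              stem_len_target = 35L,
                              loop_sequence = "CUGUGAAGCCACAGAUGGG",
                              flank_unstructured_len = 10L,
                              max_pri_len = 200L,
                              max_attempts = 50L,
                              cnnc_window = c(16L, 21L)) {
  basal_dinucleotide <- as_rna(basal_dinucleotide, "basal_dinucleotide")
  if (nchar(basal_dinucleotide) != 2L) {
    stop("basal_dinucleotide must be a 2-mer", call. = FALSE)
  }
  chc_bulge_nt <- as_rna(chc_bulge_nt, "chc_bulge_nt")
  if (!chc_bulge_nt %in% c("A", "C", "U")) {
    stop("chc_bulge_nt (H) must be one of A, C, U", call. = FALSE)
  }
  chc_strand <- match.arg(chc_strand, "3p")
  stopifnot(is_interval(debulge_window))
  chc_offset <- as.integer(chc_offset)
  if (chc_offset < debulge_window[1] || chc_offset > debulge_window[2]) {
    stop("chc_offset must lie within the debulge window", call. = FALSE)
  }
  if (!nzchar(loop_sequence %||% "")) {
    stop("loop_sequence must be a non-empty RNA string", call. = FALSE)
  }
  loop_sequence <- as_rna(loop_sequence, "loop_sequence")
  structure(
    list(basal_dinucleotide = basal_dinucleotide,
         chc_offset = chc_offset,
         chc_bulge_nt = chc_bulge_nt,
         chc_strand = chc_strand,
         debulge_window = as.integer(debulge_window),
         stem_len_target = as.integer(stem_len_target),
         loop_sequence = loop_sequence,
         flank_unstructured_len = as.integer(flank_unstructured_len),
         max_pri_len = as.integer(max_pri_len),
         max_attempts = as.integer(max_attempts),
         cnnc_window = as.integer(cnnc_window)),
    class = "ModificationSpec"
  )
}

#' @export
print.ModificationSpec <- function(x, ...) {
  cat("ModificationSpec\n")
  cat("  basal dinucleotide (-14/-13):", x$basal_dinucleotide, "\n")
  cat("  CHC bulge:", x$chc_bulge_nt, "at offset", x$chc_offset,
      "on the", x$chc_strand, "strand\n")
  cat("  debulge window:", x$debulge_window[1], "..", x$debulge_window[2], "\n")
  cat("  stem target:", x$stem_len_target, "bp\n")
  cat("  loop:", x$loop_sequence, "\n")
  cat("  unstructured flanks:", x$flank_unstructured_len, "nt\n")
  invisible(x)
}
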