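#' Build flank-extended reference windows for read quantification
#'
#' For each mature strand (guide and passenger) of a scaffold, builds the
#' per-scaffold alignment reference used by the quantification and
#' precision analyses: the mature strand ("core") extended by `flank_len`
#' scaffold bases on each side. For the canonical 22-nt mature strand and
#' the default 10-base flanks this yields a 42-base window. Each scaffold
#' gets its own pair of windows, so reads can never cross-map between
#' scaffolds.
#'
#' Windows are emitted in the sequencing (DNA) alphabet, the core region
#' uppercase and the flanks lowercase, mirroring the way precision plots
#' label the mature strand against its flanks.
#'
#' @param s An `EngineeredScaffold` (or [pri_mirna()]; arms then play the
#'   roles of guide and passenger per `guide_arm`).
#' @param flank_len Flank length in bases (default 10).
#' @return A named list with elements `guide` and `passenger`, each a
#'   `ReferenceWindow`: `id`, `scaffold_id`, `role`, `core`, `left_flank`,
#'   `right_flank`, `window` (DNA, case-marked), `core_start`/`core_end`
#'   (1-based positions of the core inside the window).
#' @export
build_reference_windows <- function(s, flank_len = 10L) {
  st <- new_design_state(s)
  garm <- st$guide_arm %||% "5p"
  arms <- list(`5p` = st$arm5p, `3p` = st$arm3p)
  roles <- if (garm == "5p") c(guide = "5p", passenger = "3p") else
    c(guide = "3p", passenger = "5p")
  n <- nchar(st$seq)
  out <- list()
  for (role in names(roles)) {
    iv <- arms[[roles[[role]]]]
    if (iv[1] - flank_len < 1L) {
      stop("insufficient scaffold sequence on the 5' side of the ", role,
           " strand for a ", flank_len, "-base flank", call. = FALSE)
    }
    if (iv[2] + flank_len > n) {
      stop("insufficient scaffold sequence on the 3' side of the ", role,
           " strand for a ", flank_len, "-base flank", call. = FALSE)
    }
    core <- substr(st$seq, iv[1], iv[2])
    left <- if (flank_len > 0L) substr(st$seq, iv[1] - flank_len, iv[1] - 1L) else ""
    right <- if (flank_len > 0L) substr(st$seq, iv[2] + 1L, iv[2] + flank_len) else ""
    win <- paste0(tolower(as_dna(left)), as_dna(core), tolower(as_dna(right)))
    out[[role]] <- structure(
      list(id = paste0(st$id, "_", role), scaffold_id = st$id, role = role,
           core = core, left_flank = left, right_flank = right,
           window = win, flank_len = as.integer(flank_len),
           core_start = flank_len + 1L,
           core_end = flank_len + nchar(core)),
      class = "ReferenceWindow"
    )
  }
  out
}

#' @export
print.ReferenceWindow <- function(x, ...) {
  cat("ReferenceWindow", x$id, "(", nchar(x$window), "bases )\n")
  cat(" ", x$window, "\n")
  cat("  core:", x$core_start, "-", x$core_end, "\n")
  invisible(x)
}

#' Write reference windows to FASTA
#'
#' @param windows List of `ReferenceWindow` objects (or the list returned
#'   by [build_reference_windows()]).
#' @param path Output FASTA path.
#' @export
write_windows_fasta <- function(windows, path) {
  seqs <- vapply(windows, function(w) w$window, character(1))
  names(seqs) <- vapply(windows, function(w) w$id, character(1))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
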