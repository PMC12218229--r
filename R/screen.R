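#' Screen candidate pri-miRNAs by expression and CNNC motif
#'
#' Selects reference pri-miRNAs for scaffold engineering the way the
#' original candidate set was chosen: keep candidates carrying a CNNC motif
#' in the canonical window downstream of the 3p DROSHA site, rank by
#' expression, and take the top `top_n`.
#'
#' The CNNC motif (C, any, any, C) must start 16-21 nt (configurable via
#' `spec$cnnc_window`) downstream of the 3' end of the 3p arm. Ties in
#' abundance are broken lexicographically by id so the ranking is
#' reproducible.
#'
#' @param expression Named non-negative numeric vector: abundance per
#'   candidate id.
#' @param candidates Named list of [pri_mirna()] objects covering the ids.
#' @param top_n Number of candidates to return (default 15).
#' @param spec A [modification_spec()] supplying the CNNC window.
#' @return A data.frame with columns `id`, `abundance`, `cnnc_offset`
#'   (downstream offset of the motif start, 1 = first base after the 3p
#'   arm) and `cnnc_motif`, ranked by decreasing abundance.
#' @export
screen_candidates <- function(expression, candidates, top_n = 15L,
                              spec = modification_spec()) {
  if (!length(expression)) stop("empty expression table", call. = FALSE)
  if (is.null(names(expression)) || any(!nzchar(names(expression)))) {
    stop("expression must be a named vector", call. = FALSE)
  }
  if (any(expression < 0)) stop("abundance values must be non-negative",
                                call. = FALSE)
  w <- spec$cnnc_window
  rows <- list()
  for (id in names(expression)) {
    p <- candidates[[id]]
    if (is.null(p)) stop("no sequence for candidate ", id, call. = FALSE)
    flank <- substr(p$sequence, p$arm3p[2] + 1L, nchar(p$sequence))
    hit <- NA_integer_; motif <- NA_character_
    for (k in seq(w[1], w[2])) {
      m <- substr(flank, k, k + 3L)
      if (nchar(m) == 4L && substr(m, 1, 1) == "C" && substr(m, 4, 4) == "C") {
        hit <- k; motif <- m; break
      }
    }
    if (!is.na(hit)) {
      rows[[id]] <- data.frame(id = id, abundance = unname(expression[[id]]),
                               cnnc_offset = hit, cnnc_motif = motif)
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(0), abundance = numeric(0),
                      cnnc_offset = integer(0), cnnc_motif = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$abundance, out$id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
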