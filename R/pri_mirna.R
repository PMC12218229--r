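#' Construct an annotated pri-miRNA
#'
#' A `PriMiRNA` bundles a primary-miRNA sequence (at most `max_len`
#' nucleotides, the length budget used for subcloning) with the 1-based
#' closed intervals of its annotated mature 5p and 3p arms. The 5p arm must
#' end before the 3p arm starts and both arms must be 18-25 nt, the mature
#' miRNA length range.
#'
#' @param id Identifier.
#' @param sequence RNA (or DNA) string.
#' @param arm5p,arm3p Integer vectors `c(start, end)`, 1-based closed.
#' @param max_len Maximum pri-miRNA length (default 200 nt).
#' @return A `PriMiRNA` object.
#' @examples
#' p <- pri_mirna("toy", paste(rep("ACGU", 20), collapse = ""),
#'                c(5, 26), c(45, 66))
#' @export
pri_mirna <- function(id, sequence, arm5p, arm3p, max_len = 200L) {
  sequence <- as_rna(sequence, paste0("sequence of ", id))
  n <- nchar(sequence)
  if (n > max_len) {
    stop("pri-miRNA ", id, " exceeds the maximum length of ", max_len, " nt",
         call. = FALSE)
  }
  stopifnot(is_interval(arm5p), is_interval(arm3p))
  arm5p <- as.integer(arm5p); arm3p <- as.integer(arm3p)
  if (arm5p[1] < 1L || arm3p[2] > n) {
    stop("arm intervals of ", id, " fall outside the sequence", call. = FALSE)
  }
  if (arm5p[2] >= arm3p[1]) {
    stop("5p arm of ", id, " must end before the 3p arm starts", call. = FALSE)
  }
  for (len in c(diff(arm5p), diff(arm3p)) + 1L) {
    if (len < 18L || len > 25L) {
      stop("mature arms of ", id, " must be 18-25 nt (got ", len, ")",
           call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence,
                 arm5p = arm5p, arm3p = arm3p),
            class = "PriMiRNA")
}

#' @export
print.PriMiRNA <- function(x, ...) {
  cat("PriMiRNA", x$id, "(", nchar(x$sequence), "nt )\n")
  cat("  5p arm:", x$arm5p[1], "-", x$arm5p[2], " ",
      substr_interval(x$sequence, x$arm5p), "\n")
  cat("  3p arm:", x$arm3p[1], "-", x$arm3p[2], " ",
      substr_interval(x$sequence, x$arm3p), "\n")
  invisible(x)
}

#' Read pri-miRNAs from FASTA plus an arm-annotation table
#'
#' The annotation TSV has columns `id`, `arm5p_start`, `arm5p_end`,
#' `arm3p_start`, `arm3p_end` with 1-based closed intervals. Every annotated
#' id must be present in the FASTA.
#'
#' @param fasta Path to a FASTA file (DNA or RNA).
#' @param annot Path to the annotation TSV.
#' @param max_len Maximum pri-miRNA length.
#' @return Named list of [pri_mirna()] objects.
#' @export
read_pri_mirna <- function(fasta, annot, max_len = 200L) {
  seqs <- Biostrings::readBStringSet(fasta)
  tab <- utils::read.delim(annot, stringsAsFactors = FALSE)
  need <- c("id", "arm5p_start", "arm5p_end", "arm3p_start", "arm3p_end")
  if (!all(need %in% names(tab))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  # FASTA headers may carry descriptions after the id
  ids <- sub("\\s.*$", "", names(seqs))
  out <- list()
  for (k in seq_len(nrow(tab))) {
    row <- tab[k, ]
    hit <- match(row$id, ids)
    if (is.na(hit)) stop("annotated id not in FASTA: ", row$id, call. = FALSE)
    out[[row$id]] <- pri_mirna(
      row$id, as.character(seqs[[hit]]),
      c(row$arm5p_start, row$arm5p_end),
      c(row$arm3p_start, row$arm3p_end),
      max_len = max_len
    )
  }
  out
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param x Named character vector of sequences, or a single `PriMiRNA` /
#'   `EngineeredScaffold`.
#' @param path Output path.
#' @param alphabet `"rna"` or `"dna"` output alphabet.
#' @export
write_fasta <- function(x, path, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  if (inherits(x, "PriMiRNA")) x <- stats::setNames(x$sequence, x$id)
  if (inherits(x, "EngineeredScaffold")) x <- stats::setNames(x$sequence, x$id)
  if (alphabet == "dna") x <- vapply(x, as_dna, character(1))
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Bundled example pri-miRNAs
#'
#' Loads the packaged pri-let-7a-1 / pri-miR-26b examples: the miRBase
#' hairpin with its annotated mature arms, embedded in a synthetic flanking
#' context (the natural genomic flanks are not bundled; the synthetic flanks
#' are engineered to stay unstructured and to carry a CNNC motif in the
#' canonical downstream window).
#'
#' @param which `"let7a1"` or `"mir26b"`; `NULL` returns both.
#' @return A `PriMiRNA`, or a named list of them.
#' @export
amirna_fixture <- function(which = NULL) {
  fa <- system.file("extdata", "synthetic_pri_mirna.fa", package = "amirna")
  an <- system.file("extdata", "synthetic_pri_mirna_annot.tsv",
                    package = "amirna")
  all <- suppressMessages(read_pri_mirna(fa, an))
  key <- c(let7a1 = "pri-let-7a-1", mir26b = "pri-miR-26b")
  if (is.null(which)) return(all)
  nm <- key[[match.arg(which, names(key))]]
  all[[nm]]
}
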