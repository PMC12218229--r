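# Read ingestion, strict classification, strand counting and
# processing-precision profiling.

#' Read small-RNA alignments from SAM or BAM
#'
#' SAM text files are converted on the fly (via Rsamtools) and records are
#' returned as a plain data.frame, one row per alignment: `qname`, `flag`,
#' `window` (reference name), `pos` (1-based leftmost), `cigar`, `seq`.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return data.frame of read records.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(
    qname = res$qname,
    flag = res$flag,
    window = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar,
    seq = as.character(res$seq),
    stringsAsFactors = FALSE
  )
}

#' Classify reads by the strict full-length-match criteria
#'
#' A read is accepted iff (a) its CIGAR is a single match run (`<n>M`,
#' e.g. `22M`) -- no insertions, deletions or clipping -- and (b) the match
#' length lies within `[min_len, max_len]` (default 18-24 nt, the mature
#' miRNA band), and (c) its flags pass the filter: mapped, primary,
#' forward-strand (reads are sense copies of the hairpin arms). Each
#' rejected read carries a machine-readable reason.
#'
#' `M` is treated as alignment match (substitutions tolerated); the
#' criteria constrain only indels and length.
#'
#' @param reads data.frame from [read_alignments()] (or the simulator).
#' @param min_len,max_len Accepted read-length band.
#' @return The input with `len`, `accept` (logical) and `reason`
#'   (`NA` for accepted reads) columns appended.
#' @export
classify_reads <- function(reads, min_len = 18L, max_len = 24L) {
  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  cig <- reads$cigar
  bad_chars <- grepl("[^0-9MIDNSHP=X]", cig)
  if (any(bad_chars, na.rm = TRUE)) {
    stop("malformed CIGAR: ", cig[which(bad_chars)[1]], call. = FALSE)
  }
  flag <- reads$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  reverse <- bitwAnd(flag, 16L) != 0L
  pure <- grepl("^[0-9]+M$", cig)
  has_indel <- grepl("[ID]", cig)
  has_clip <- grepl("[SH]", cig)
  len <- ifelse(pure, suppressWarnings(as.integer(sub("M$", "", cig))),
                NA_integer_)
  reason[!pure] <- "invalid_cigar"
  reason[!pure & has_clip] <- "clipped"
  reason[!pure & has_indel] <- "indel"
  reason[pure & len < min_len] <- "too_short"
  reason[pure & len > max_len] <- "too_long"
  reason[reverse] <- "reverse_strand"
  reason[supplementary] <- "supplementary"
  reason[secondary] <- "secondary"
  reason[unmapped] <- "unmapped"
  reads$len <- len
  reads$accept <- is.na(reason)
  reads$reason <- reason
  reads
}

#' Count accepted reads per strand
#'
#' Partitions accepted reads between the guide and passenger windows of a
#' scaffold and reports raw and normalized counts. Normalization is
#' reads-per-million classified reads by default (one shared library-size
#' factor), configurable via `library_size`.
#'
#' @param reads Classified data.frame ([classify_reads()]); only accepted
#'   rows are counted.
#' @param windows Window pair from [build_reference_windows()].
#' @param library_size Total used for the per-million factor; defaults to
#'   the number of accepted reads.
#' @return A `StrandCounts` object: `guide_count`, `passenger_count`,
#'   `normalized_guide`, `normalized_passenger`, `library_size`.
#' @export
count_strands <- function(reads, windows, library_size = NULL) {
  acc <- reads[reads$accept, , drop = FALSE]
  ids <- c(guide = windows$guide$id, passenger = windows$passenger$id)
  unknown <- setdiff(unique(acc$window), ids)
  if (length(unknown)) {
    stop("reads assigned to unknown window(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  g <- sum(acc$window == ids[["guide"]])
  p <- sum(acc$window == ids[["passenger"]])
  lib <- library_size %||% nrow(acc)
  norm <- function(x) if (lib > 0) x / lib * 1e6 else NA_real_
  structure(
    list(guide_count = g, passenger_count = p,
         normalized_guide = norm(g), normalized_passenger = norm(p),
         library_size = lib, scaffold_id = windows$guide$scaffold_id),
    class = "StrandCounts"
  )
}

#' @export
print.StrandCounts <- function(x, ...) {
  cat("StrandCounts", x$scaffold_id %||% "", "\n")
  cat(sprintf("  guide:     %8d (%.1f RPM)\n", x$guide_count,
              x$normalized_guide))
  cat(sprintf("  passenger: %8d (%.1f RPM)\n", x$passenger_count,
              x$normalized_passenger))
  invisible(x)
}

#' Guide:passenger abundance ratio
#'
#' Fold-change of raw guide over passenger counts. A zero passenger count
#' with a positive guide count yields `Inf` with `infinite = TRUE` (a
#' flagged sentinel, not an error); two zero counts are an error.
#'
#' @param counts A `StrandCounts` object.
#' @return List with `ratio`, `infinite`, `guide_count`, `passenger_count`.
#' @export
guide_passenger_ratio <- function(counts) {
  g <- counts$guide_count; p <- counts$passenger_count
  if (g == 0L && p == 0L) {
    stop("undefined guide:passenger ratio: no reads on either strand",
         call. = FALSE)
  }
  if (p == 0L) {
    return(list(ratio = Inf, infinite = TRUE, guide_count = g,
                passenger_count = p))
  }
  list(ratio = g / p, infinite = FALSE, guide_count = g, passenger_count = p)
}

#' Processing-precision profile over a reference window
#'
#' Tabulates, per window position, the percentage of accepted reads whose
#' alignment starts (resp. ends) there. The 5' fidelity is the start
#' percentage at the expected core start -- the fraction of reads beginning
#' exactly at the intended mature 5' nucleotide, which determines seed
#' homogeneity.
#'
#' @param reads Classified data.frame; only accepted rows mapped to
#'   `window` are used.
#' @param window A `ReferenceWindow`.
#' @return A `PrecisionProfile`: `position` (1-based window coordinates),
#'   `start_count`/`start_pct`, `end_count`/`end_pct`, `expected_start`,
#'   `expected_end`, `five_prime_fidelity`, `three_prime_fidelity`,
#'   `n_reads`.
#' @export
precision_profile <- function(reads, window) {
  acc <- reads[reads$accept & reads$window == window$id, , drop = FALSE]
  if (!nrow(acc)) {
    stop("no accepted reads for window ", window$id,
         "; precision profile undefined", call. = FALSE)
  }
  W <- nchar(window$window)
  starts <- acc$pos
  ends <- acc$pos + acc$len - 1L
  if (any(starts < 1L | ends > W)) {
    stop("read coordinates fall outside the window", call. = FALSE)
  }
  sc <- tabulate(starts, nbins = W)
  ec <- tabulate(ends, nbins = W)
  n <- nrow(acc)
  prof <- structure(
    list(window_id = window$id, position = seq_len(W),
         start_count = sc, start_pct = 100 * sc / n,
         end_count = ec, end_pct = 100 * ec / n,
         expected_start = window$core_start,
         expected_end = window$core_end,
         five_prime_fidelity = 100 * sc[window$core_start] / n,
         three_prime_fidelity = 100 * ec[window$core_end] / n,
         n_reads = n),
    class = "PrecisionProfile"
  )
  prof
}

#' @export
print.PrecisionProfile <- function(x, ...) {
  cat("PrecisionProfile", x$window_id, "(", x$n_reads, "reads )\n")
  cat(sprintf("  5' fidelity: %.2f%% at window position %d\n",
              x$five_prime_fidelity, x$expected_start))
  cat(sprintf("  3' fidelity: %.2f%% at window position %d\n",
              x$three_prime_fidelity, x$expected_end))
  invisible(x)
}

#' @export
as.data.frame.PrecisionProfile <- function(x, ...) {
  data.frame(window = x$window_id, position = x$position,
             start_count = x$start_count, start_pct = x$start_pct,
             end_count = x$end_count, end_pct = x$end_pct)
}

#' @export
plot.PrecisionProfile <- function(x, which = c("start", "end"), ...) {
  which <- match.arg(which)
  v <- if (which == "start") x$start_pct else x$end_pct
  graphics::barplot(v, names.arg = x$position,
                    xlab = "window position", ylab = paste0(which, " %"),
                    main = x$window_id, ...)
  invisible(x)
}

#' Write profiles and counts as a TSV table
#'
#' One row per window position with start/end counts and percentages, the
#' layout used for precision-plot input.
#'
#' @param profiles List of `PrecisionProfile` objects.
#' @param path Output TSV path.
#' @export
write_profile_tsv <- function(profiles, path) {
  tabs <- lapply(profiles, as.data.frame)
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exact-substring alignment of reads to reference windows
#'
#' A deliberately naive aligner bundled so the FASTQ path of the pipeline
#' can be exercised without an external aligner: each read is placed at the
#' unique exact, case-insensitive, U/T-equivalent occurrence in one of the
#' windows. Reads matching nowhere are flagged unmapped; reads matching
#' more than one window (or more than once) are assigned to the first hit
#' and logged as ties.
#'
#' @param seqs Character vector of read sequences (DNA or RNA), optionally
#'   named.
#' @param windows List of `ReferenceWindow` objects.
#' @return data.frame in the layout of [read_alignments()].
#' @export
align_exact <- function(seqs, windows) {
  wins <- lapply(windows, function(w) toupper(as_dna(w$window)))
  ids <- vapply(windows, function(w) w$id, character(1))
  qn <- names(seqs) %||% sprintf("read%06d", seq_along(seqs))
  rows <- vector("list", length(seqs))
  ties <- 0L
  for (k in seq_along(seqs)) {
    s <- toupper(as_dna(seqs[[k]]))
    hits <- list()
    for (wi in seq_along(wins)) {
      at <- gregexpr(s, wins[[wi]], fixed = TRUE)[[1]]
      if (at[1] != -1L) for (a in at) hits[[length(hits) + 1L]] <- c(wi, a)
    }
    if (!length(hits)) {
      rows[[k]] <- data.frame(qname = qn[k], flag = 4L,
                              window = NA_character_, pos = NA_integer_,
                              cigar = "*", seq = s)
      next
    }
    if (length(hits) > 1L) ties <- ties + 1L
    h <- hits[[1]]
    rows[[k]] <- data.frame(qname = qn[k], flag = 0L, window = ids[h[1]],
                            pos = h[2], cigar = paste0(nchar(s), "M"),
                            seq = s)
  }
  out <- do.call(rbind, rows)
  attr(out, "ties") <- ties
  out
}
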