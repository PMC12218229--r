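#' Minimum-free-energy folding service backed by ViennaRNA RNAfold
#'
#' The design engine never computes thermodynamics itself: secondary
#' structure is obtained from an injected *folding service*, a deterministic
#' function `sequence -> dot-bracket string` of equal length. This
#' constructor wraps the `RNAfold` command-line program (ViennaRNA) and
#' memoises results, so the iterative redesign loops do not re-fold
#' sequences they have already seen.
#'
#' Any function with the same contract can be passed wherever a
#' `service` argument is accepted, e.g. a table lookup in tests.
#'
#' @param rnafold Path to the `RNAfold` executable.
#' @return A function taking one RNA string and returning its MFE
#'   dot-bracket structure.
#' @examples
#' \dontrun{
#' svc <- rnafold_service()
#' svc("GGGAAACCC")  # "(((...)))"
#' }
#' @export
rnafold_service <- function(rnafold = Sys.which("RNAfold")) {
  if (!nzchar(rnafold)) {
    stop("RNAfold executable not found; install ViennaRNA or inject a ",
         "custom folding service", call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  function(sequence) {
    sequence <- as_rna(sequence)
    hit <- get0(sequence, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    out <- suppressWarnings(
      system2(rnafold, c("--noPS"), input = sequence, stdout = TRUE)
    )
    if (length(out) < 2L) stop("RNAfold produced no structure", call. = FALSE)
    struct <- sub("^([().]+).*$", "\\1", out[2])
    if (nchar(struct) != nchar(sequence)) {
      stop("RNAfold structure length does not match input", call. = FALSE)
    }
    assign(sequence, struct, envir = cache)
    struct
  }
}

# Parse a dot-bracket string into a pair table: integer vector where
# entry i is the partner of position i, or NA when unpaired.
#' @keywords internal
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad)) {
    stop("unsupported characters in dot-bracket: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  n <- length(chars)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i
      pt[i] <- j
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
  pt
}

# All hairpin (terminal) loops in a pair table: closing pairs (i, j) with no
# paired position strictly between them.
#' @keywords internal
hairpin_loops <- function(pt) {
  res <- list()
  for (i in which(!is.na(pt))) {
    j <- pt[i]
    if (j > i && (j == i + 1L || all(is.na(pt[(i + 1L):(j - 1L)])))) {
      res[[length(res) + 1L]] <- c(start = i + 1L, end = j - 1L)
    }
  }
  res
}

#' Fold a sequence and validate single-hairpin topology
#'
#' Runs the folding service and wraps the result in a `FoldedHairpin`
#' object: sequence, dot-bracket, pair table, terminal-loop interval and the
#' coordinate anchor. When mature-arm intervals are supplied, the region
#' from the start of the 5p arm to the end of the 3p arm must contain
#' exactly one terminal loop, located between the two arms; otherwise a
#' "not a hairpin" error is raised.
#'
#' The anchor is the 5'-most nucleotide of the 5p arm -- the putative DROSHA
#' 5' cleavage site -- and defines signed offsets: `offset = index - anchor`,
#' so offset 0 is the cleavage site and negative offsets run into the basal
#' stem and flank.
#'
#' @param sequence RNA (or DNA, auto-converted) string.
#' @param service A folding service, see [rnafold_service()].
#' @param arm5p,arm3p Optional 1-based closed intervals of the mature arms.
#' @param id Optional identifier carried through to reports.
#' @return A `FoldedHairpin` object.
#' @export
fold <- function(sequence, service = rnafold_service(),
                 arm5p = NULL, arm3p = NULL, id = NULL) {
  sequence <- as_rna(sequence)
  structure <- service(sequence)
  pt <- pair_table(structure)
  # involution sanity: partner of my partner is me
  idx <- which(!is.na(pt))
  stopifnot(all(pt[pt[idx]] == idx))
  loops <- hairpin_loops(pt)
  loop <- NULL
  anchor <- NA_integer_
  if (!is.null(arm5p) && !is.null(arm3p)) {
    stopifnot(is_interval(arm5p), is_interval(arm3p))
    anchor <- as.integer(arm5p[1])
    between <- Filter(function(l) l["start"] > arm5p[2] && l["end"] < arm3p[1],
                      loops)
    inside <- Filter(function(l) l["start"] >= arm5p[1] && l["end"] <= arm3p[2],
                     loops)
    if (length(inside) != 1L || length(between) != 1L) {
      stop("not a hairpin: expected exactly one terminal loop between the ",
           "annotated arms, found ", length(inside), call. = FALSE)
    }
    loop <- as.integer(between[[1]])
  } else if (length(loops) == 1L) {
    loop <- as.integer(loops[[1]])
  }
  structure(
    list(id = id, sequence = sequence, structure = structure,
         pair_table = pt, loop = loop, anchor = anchor,
         arm5p = if (!is.null(arm5p)) as.integer(arm5p),
         arm3p = if (!is.null(arm3p)) as.integer(arm3p)),
    class = "FoldedHairpin"
  )
}

#' @export
print.FoldedHairpin <- function(x, ...) {
  cat("FoldedHairpin", if (!is.null(x$id)) x$id else "", "\n")
  cat(x$sequence, "\n")
  cat(x$structure, "\n")
  if (!is.null(x$loop)) {
    cat("terminal loop:", x$loop[1], "-", x$loop[2], "\n")
  }
  if (!is.na(x$anchor)) cat("anchor (offset 0):", x$anchor, "\n")
  invisible(x)
}

#' Convert between absolute indices and DROSHA-anchored offsets
#'
#' @param h A `FoldedHairpin` with a defined anchor.
#' @param index,offset Integer vectors.
#' @return Integer vector of offsets (resp. indices).
#' @export
offset_of <- function(h, index) {
  stopifnot(inherits(h, "FoldedHairpin"), !is.na(h$anchor))
  as.integer(index) - h$anchor
}

#' @rdname offset_of
#' @export
index_of <- function(h, offset) {
  stopifnot(inherits(h, "FoldedHairpin"), !is.na(h$anchor))
  h$anchor + as.integer(offset)
}

#' Extract the stem of a folded hairpin
#'
#' Walks outward from the loop-closing pair, collecting the run of base
#' pairs down to the basal junction. Bulged / internal-loop positions do not
#' interrupt the run as long as the unpaired gap between consecutive pairs
#' stays within `max_gap` on both strands; a larger gap is treated as the
#' basal junction (an "unstructured base of the stem"). Paired positions
#' only are counted, matching the convention that a 35-bp stem means 13
#' basal pairs plus a 22-bp mature duplex.
#'
#' When the hairpin carries mature-arm annotations, the stem is truncated
#' at the top of the duplex: pairs whose 5'-side position lies beyond the
#' end of the 5p arm belong to the (possibly internally structured) loop
#' region and are not counted. The loop-proximal stem pair is then the top
#' pair of the mature duplex.
#'
#' @param h A `FoldedHairpin` whose terminal loop is defined.
#' @param max_gap Largest unpaired stretch (nt, per strand) bridged within
#'   the stem.
#' @return A list with `pairs` (data.frame `i`, `j`, ordered basal to
#'   loop-proximal, plus `offset5` when the anchor is known), `n_pairs`, and
#'   `bulges` (data.frame of unpaired positions inside the stem with their
#'   strand).
#' @export
stem_pairs <- function(h, max_gap = 6L) {
  stopifnot(inherits(h, "FoldedHairpin"))
  if (is.null(h$loop)) stop("hairpin has no identified terminal loop", call. = FALSE)
  pt <- h$pair_table
  i <- h$loop[1] - 1L
  j <- h$loop[2] + 1L
  if (i < 1L || j > length(pt) || is.na(pt[i]) || pt[i] != j) {
    stop("terminal loop is not closed by a base pair", call. = FALSE)
  }
  is5 <- i; js <- j
  bulge_pos <- integer(0); bulge_strand <- character(0)
  repeat {
    ni <- i - 1L
    while (ni >= 1L && is.na(pt[ni])) ni <- ni - 1L
    nj <- j + 1L
    while (nj <= length(pt) && is.na(pt[nj])) nj <- nj + 1L
    gap5 <- i - ni - 1L
    gap3 <- nj - j - 1L
    if (ni < 1L || nj > length(pt) || pt[ni] != nj ||
        gap5 > max_gap || gap3 > max_gap) break
    if (gap5 > 0L) {
      bulge_pos <- c(bulge_pos, (ni + 1L):(i - 1L))
      bulge_strand <- c(bulge_strand, rep("5p", gap5))
    }
    if (gap3 > 0L) {
      bulge_pos <- c(bulge_pos, (j + 1L):(nj - 1L))
      bulge_strand <- c(bulge_strand, rep("3p", gap3))
    }
    i <- ni; j <- nj
    is5 <- c(is5, i); js <- c(js, j)
  }
  ord <- order(is5)  # basal -> loop-proximal is increasing i
  pairs <- data.frame(i = is5[ord], j = js[ord])
  bulges <- data.frame(pos = bulge_pos, strand = bulge_strand)
  if (!is.null(h$arm5p)) {
    # truncate at the duplex top; loop-internal helix pairs are not stem
    pairs <- pairs[pairs$i <= h$arm5p[2], , drop = FALSE]
    bulges <- bulges[bulges$pos <= h$arm5p[2] | bulges$pos >= h$arm3p[1], ,
                     drop = FALSE]
  }
  if (!is.na(h$anchor)) {
    pairs$offset5 <- pairs$i - h$anchor
    bulges$offset <- bulges$pos - h$anchor
  }
  list(pairs = pairs, n_pairs = nrow(pairs), bulges = bulges)
}

#' Write sequence + structure in Vienna format
#'
#' @param h A `FoldedHairpin`.
#' @param path Output file; when `NULL` the two lines are returned.
#' @export
write_vienna <- function(h, path = NULL) {
  stopifnot(inherits(h, "FoldedHairpin"))
  lines <- c(paste0(">", h$id %||% "hairpin"), h$sequence, h$structure)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
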