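`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalise a nucleotide string to the internal RNA alphabet
#'
#' Uppercases the input and converts `T` to `U`. DNA input is accepted
#' everywhere a sequence is taken; a message is emitted once per call when a
#' conversion actually happens.
#'
#' @param x Character scalar over `A/C/G/U/T` (case-insensitive).
#' @param what Label used in error messages.
#' @return Character scalar over `A/C/G/U`.
#' @keywords internal
as_rna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  }
  x <- toupper(x)
  if (grepl("T", x, fixed = TRUE)) {
    message("converting T to U in ", what, " (DNA input accepted)")
    x <- gsub("T", "U", x, fixed = TRUE)
  }
  if (grepl("[^ACGU]", x)) {
    stop(what, " contains characters outside A/C/G/U/T", call. = FALSE)
  }
  x
}

#' @keywords internal
as_dna <- function(x) chartr("Uu", "Tt", x)

# Reverse complement of an RNA string (thin wrapper over Biostrings).
#' @keywords internal
rc_rna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

# A nucleotide guaranteed not to form a Watson-Crick or GU pair with `x`.
NONPAIRING <- c(A = "C", C = "A", G = "A", U = "C")

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' `.Random.seed` afterwards, so seeded package internals never perturb the
#' user's RNG stream.
#' @keywords internal
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Sample an RNA string of length n from `alphabet`, rejecting homopolymer
# runs of length >= max_run. Used for basal-stem extensions and flanks.
#' @keywords internal
sample_rna <- function(n, alphabet = c("A", "C", "G", "U"), max_run = 3L) {
  if (n <= 0L) return("")
  repeat {
    s <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
    if (!grepl(sprintf("([ACGU])\\1{%d,}", max_run), s)) return(s)
  }
}

#' @keywords internal
is_interval <- function(x) {
  is.numeric(x) && length(x) == 2L && !anyNA(x) && x[1] <= x[2]
}

#' @keywords internal
substr_interval <- function(seq, iv) substr(seq, iv[1], iv[2])
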