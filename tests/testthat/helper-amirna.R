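# Shared test infrastructure: one memoised folding service for the whole
# session, lazily built fixture scaffolds, and a fake folding service for
# structure-logic tests that should not depend on thermodynamics.

.amirna_test_cache <- new.env(parent = emptyenv())

test_service <- function() {
  svc <- get0("service", envir = .amirna_test_cache)
  if (is.null(svc)) {
    svc <- rnafold_service()
    assign("service", svc, envir = .amirna_test_cache)
  }
  svc
}

cached <- function(key, expr) {
  v <- get0(key, envir = .amirna_test_cache)
  if (is.null(v)) {
    v <- force(expr)
    assign(key, v, envir = .amirna_test_cache)
  }
  v
}

fixture_parent <- function(which) {
  cached(paste0("parent_", which), amirna_fixture(which))
}

fixture_all <- function(which = "mir26b", seed = 7L) {
  cached(paste0("all_", which, "_", seed),
         apply_all(fixture_parent(which), service = test_service(),
                   seed = seed))
}

fixture_base <- function(which = "let7a1", seed = 7L) {
  cached(paste0("base_", which, "_", seed),
         apply_base_modification(fixture_parent(which),
                                 service = test_service(), seed = seed))
}

# folding service that replays a fixed table of structures: used to test
# structure-handling logic with hand-written dot-brackets
table_service <- function(tbl) {
  function(sequence) {
    s <- tbl[[sequence]]
    if (is.null(s)) stop("table_service: unknown sequence ", sequence)
    s
  }
}

# independent brute-force CIGAR parser used as the classification oracle
oracle_classify <- function(flag, cigar, min_len = 18, max_len = 24) {
  if (bitwAnd(flag, 4L) != 0L) return("unmapped")
  if (bitwAnd(flag, 256L) != 0L) return("secondary")
  if (bitwAnd(flag, 2048L) != 0L) return("supplementary")
  if (bitwAnd(flag, 16L) != 0L) return("reverse_strand")
  ops <- character(0); lens <- integer(0); num <- ""
  for (ch in strsplit(cigar, "")[[1]]) {
    if (grepl("[0-9]", ch)) {
      num <- paste0(num, ch)
    } else {
      ops <- c(ops, ch); lens <- c(lens, as.integer(num)); num <- ""
    }
  }
  if (!identical(unique(ops), "M") || length(ops) != 1L) {
    if (any(ops %in% c("I", "D"))) return("indel")
    if (any(ops %in% c("S", "H"))) return("clipped")
    return("invalid_cigar")
  }
  if (lens[1] < min_len) return("too_short")
  if (lens[1] > max_len) return("too_long")
  "accept"
}

expect_identical_scaffold <- function(a, b) {
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$arm5p, b$arm5p)
  expect_identical(a$arm3p, b$arm3p)
}
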