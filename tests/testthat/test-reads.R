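# Read classification, strand counting, precision profiles and the ratio.

mk_reads <- function(cigar, flag = 0L, window = "w", pos = 11L,
                     qname = NULL) {
  n <- length(cigar)
  data.frame(
    qname = qname %||% sprintf("r%03d", seq_len(n)),
    flag = rep_len(flag, n), window = rep_len(window, n),
    pos = rep_len(pos, n), cigar = cigar,
    seq = rep_len(strrep("A", 20), n), stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("the strict full-length-match criteria accept and reject correctly", {
  r <- classify_reads(mk_reads(c("22M", "17M", "10M1I11M", "25M", "18M",
                                 "24M", "4S18M", "10M2D10M")))
  expect_equal(r$accept,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$reason[!r$accept],
               c("too_short", "indel", "too_long", "clipped", "indel"))
})

test_that("flag filtering rejects unmapped, secondary and reverse reads", {
  r <- classify_reads(mk_reads(rep("22M", 4), flag = c(0L, 4L, 256L, 16L)))
  expect_equal(r$accept, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$reason[!r$accept],
               c("unmapped", "secondary", "reverse_strand"))
})

test_that("malformed CIGAR strings raise a parse error", {
  expect_error(classify_reads(mk_reads("22Q")), "malformed CIGAR")
})

test_that("classification agrees with a brute-force CIGAR oracle on fuzzed records", {
  set.seed(11)
  n <- 1000L
  ops <- c("M", "I", "D", "S")
  cigars <- vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    paste0(sample(10:30, k, replace = TRUE),
           sample(ops, k, replace = TRUE), collapse = "")
  }, character(1))
  flags <- sample(c(0L, 0L, 0L, 4L, 16L, 256L, 2048L), n, replace = TRUE)
  got <- classify_reads(mk_reads(cigars, flag = flags))
  want <- mapply(oracle_classify, flags, cigars)
  expect_equal(ifelse(got$accept, "accept", got$reason), unname(want))
})

test_that("accepted plus rejected reads always equal the total", {
  set.seed(5)
  cigars <- sample(c("22M", "17M", "25M", "10M1I11M", "3S19M"), 200,
                   replace = TRUE)
  r <- classify_reads(mk_reads(cigars))
  expect_equal(sum(r$accept) + sum(!r$accept), nrow(r))
  expect_true(all(xor(r$accept, !is.na(r$reason))))
})

test_that("strand counting partitions accepted reads by window", {
  s <- fixture_all("mir26b")
  w <- build_reference_windows(s)
  r <- classify_reads(mk_reads(rep("22M", 10), window = w$guide$id))
  counts <- count_strands(r, w)
  expect_equal(counts$guide_count, 10L)
  expect_equal(counts$passenger_count, 0L)
  empty <- count_strands(classify_reads(mk_reads(character(0))), w)
  expect_equal(c(empty$guide_count, empty$passenger_count), c(0L, 0L))
  expect_error(count_strands(classify_reads(mk_reads("22M", window = "??")),
                             w),
               "unknown window")
})

test_that("RPM normalization shares one library-size factor", {
  s <- fixture_all("mir26b")
  w <- build_reference_windows(s)
  r <- classify_reads(mk_reads(rep("22M", 8),
                               window = c(rep(w$guide$id, 6),
                                          rep(w$passenger$id, 2))))
  counts <- count_strands(r, w)
  expect_equal(counts$normalized_guide / counts$normalized_passenger,
               counts$guide_count / counts$passenger_count)
  expect_equal(counts$normalized_guide, 6 / 8 * 1e6)
  scaled <- count_strands(r, w, library_size = 1e4)
  expect_equal(scaled$normalized_guide, 600)
})

test_that("guide:passenger ratio handles the zero-passenger sentinel", {
  mk <- function(g, p) list(guide_count = g, passenger_count = p)
  expect_equal(guide_passenger_ratio(mk(1000L, 10L))$ratio, 100)
  r0 <- guide_passenger_ratio(mk(5L, 0L))
  expect_true(is.infinite(r0$ratio) && r0$infinite)
  expect_error(guide_passenger_ratio(mk(0L, 0L)), "undefined")
})

test_that("precision percentages are exact for constructed read sets", {
  s <- embed_duplex(fixture_all("mir26b"), screening_guide(),
                    service = test_service(), seed = 7)
  w <- build_reference_windows(s)
  # all reads exactly on the core
  r <- classify_reads(mk_reads(rep("22M", 50), window = w$guide$id,
                               pos = w$guide$core_start))
  prof <- precision_profile(r, w$guide)
  expect_equal(prof$five_prime_fidelity, 100)
  expect_equal(sum(prof$start_pct > 0), 1L)
  expect_equal(sum(prof$start_pct), 100)
  # 98 of 100 at the expected start, 2 shifted by +1
  r2 <- classify_reads(mk_reads(rep("22M", 100), window = w$guide$id,
                                pos = c(rep(w$guide$core_start, 98),
                                        rep(w$guide$core_start + 1L, 2))))
  prof2 <- precision_profile(r2, w$guide)
  expect_equal(prof2$five_prime_fidelity, 98)
  expect_equal(sum(prof2$start_pct), 100, tolerance = 1e-12)
  expect_equal(sum(prof2$end_pct), 100, tolerance = 1e-12)
})

test_that("zero accepted reads is a defined error, not NaN vectors", {
  s <- fixture_all("mir26b")
  w <- build_reference_windows(s)
  r <- classify_reads(mk_reads("17M", window = w$guide$id))
  expect_error(precision_profile(r, w$guide), "no accepted reads")
})

test_that("per-scaffold isolation: merged read sets quantify like separate ones", {
  svc <- test_service()
  s1 <- embed_duplex(fixture_all("mir26b"), screening_guide(),
                     service = svc, seed = 7)
  s2 <- fixture_all("let7a1")
  w1 <- build_reference_windows(s1); w2 <- build_reference_windows(s2)
  sim1 <- simulate_reads(s1, simulation_config(n_reads = 400,
                                               guide_fraction = 0.9,
                                               seed = 21))
  sim2 <- simulate_reads(s2, simulation_config(n_reads = 300,
                                               guide_fraction = 0.8,
                                               seed = 22))
  merged <- rbind(sim1$reads, sim2$reads)
  cm <- classify_reads(merged)
  c1 <- count_strands(cm[cm$window %in% c(w1$guide$id, w1$passenger$id), ],
                      w1, library_size = 1)
  c2 <- count_strands(cm[cm$window %in% c(w2$guide$id, w2$passenger$id), ],
                      w2, library_size = 1)
  alone1 <- count_strands(classify_reads(sim1$reads), w1, library_size = 1)
  alone2 <- count_strands(classify_reads(sim2$reads), w2, library_size = 1)
  expect_equal(c1$guide_count, alone1$guide_count)
  expect_equal(c1$passenger_count, alone1$passenger_count)
  expect_equal(c2$guide_count, alone2$guide_count)
  expect_equal(c2$passenger_count, alone2$passenger_count)
})

test_that("the FASTQ -> naive aligner path reproduces the simulator's records", {
  s <- embed_duplex(fixture_all("mir26b"), screening_guide(),
                    service = test_service(), seed = 7)
  sim <- simulate_reads(s, simulation_config(n_reads = 200,
                                             guide_fraction = 0.9,
                                             seed = 13))
  al <- align_exact(stats::setNames(sim$reads$seq, sim$reads$qname),
                    sim$windows)
  mapped <- al[al$flag == 0L, ]
  expect_equal(nrow(mapped), nrow(sim$reads))
  expect_identical(mapped$window, sim$reads$window)
  expect_identical(mapped$pos, sim$reads$pos)
  expect_identical(mapped$cigar, sim$reads$cigar)
})

test_that("profile TSV export has the documented layout", {
  dir <- withr::local_tempdir()
  s <- fixture_all("mir26b")
  w <- build_reference_windows(s)
  r <- classify_reads(mk_reads(rep("22M", 5), window = w$guide$id,
                               pos = w$guide$core_start))
  path <- file.path(dir, "prof.tsv")
  write_profile_tsv(list(precision_profile(r, w$guide)), path)
  tab <- utils::read.delim(path)
  expect_named(tab, c("window", "position", "start_count", "start_pct",
                      "end_count", "end_pct"))
  expect_equal(nrow(tab), nchar(w$guide$window))
})
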