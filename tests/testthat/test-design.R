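# Design engine: the four modification classes, grafting, validation and
# the engine invariants (idempotence, locality, seeded determinism).

check_passes <- function(s, checks) {
  rep <- s$validation
  all(rep$pass[rep$check %in% checks])
}

test_that("base modification installs its three determinants on both fixtures", {
  for (which in c("let7a1", "mir26b")) {
    s <- apply_base_modification(fixture_parent(which),
                                 service = test_service(), seed = 7)
    expect_true(check_passes(s, c("basal_GU", "stem_length",
                                  "flanks_unstructured", "single_hairpin")),
                label = paste("base determinants on", which))
    fh <- fold(s$sequence, test_service(), s$arm5p, s$arm3p)
    expect_equal(stem_pairs(fh)$n_pairs, 35L)
    # basal dinucleotide sits at offsets -14/-13
    expect_identical(substr(s$sequence, s$anchor - 14, s$anchor - 13), "GU")
  }
})

test_that("CHC insertion yields the bulge in a bulge-free window", {
  for (which in c("let7a1", "mir26b")) {
    s <- apply_chc_insertion(fixture_parent(which),
                             service = test_service(), seed = 7)
    expect_true(check_passes(s, c("chc_bulge", "debulged_window")),
                label = paste("chc determinants on", which))
  }
})

test_that("chc_offset outside the debulge window is a config error", {
  expect_error(modification_spec(chc_offset = -20L), "debulge window")
})

test_that("an empty loop sequence is a config error", {
  expect_error(modification_spec(loop_sequence = ""), "non-empty")
})

test_that("loop swap writes the configured loop between the arms", {
  s <- apply_loop_swap(fixture_parent("let7a1"), service = test_service(),
                       seed = 7)
  spec <- modification_spec()
  got <- substr(s$sequence, s$arm5p[2] + 1, s$arm3p[1] - 1)
  expect_identical(got, spec$loop_sequence)
  expect_true(check_passes(s, "loop_identity"))
})

test_that("loop swap with the parent's own loop is the identity", {
  p <- fixture_parent("let7a1")
  own <- substr(p$sequence, p$arm5p[2] + 1, p$arm3p[1] - 1)
  spec <- modification_spec(loop_sequence = own)
  s <- apply_loop_swap(p, spec, service = test_service(), seed = 7)
  expect_identical(s$sequence, p$sequence)
})

test_that("apply_all passes every determinant check on both fixtures", {
  for (which in c("let7a1", "mir26b")) {
    s <- fixture_all(which)
    expect_true(all(s$validation$pass),
                label = paste("all-modification validation on", which))
    fh <- fold(s$sequence, test_service(), s$arm5p, s$arm3p)
    expect_equal(stem_pairs(fh)$n_pairs, 35L)
  }
})

test_that("every apply_* is a fixed point on its own output", {
  svc <- test_service()
  sb <- fixture_base("let7a1")
  sb2 <- apply_base_modification(as_pri_mirna(sb), service = svc, seed = 99)
  expect_identical_scaffold(sb, sb2)
  sc <- apply_chc_insertion(fixture_parent("mir26b"), service = svc, seed = 7)
  sc2 <- apply_chc_insertion(as_pri_mirna(sc), service = svc, seed = 99)
  expect_identical_scaffold(sc, sc2)
  sa <- fixture_all("mir26b")
  sa2 <- apply_all(as_pri_mirna(sa), service = svc, seed = 99)
  expect_identical_scaffold(sa, sa2)
})

test_that("same seed gives byte-identical engineered sequences", {
  a <- apply_all(fixture_parent("let7a1"), service = test_service(), seed = 11)
  b <- apply_all(fixture_parent("let7a1"), service = test_service(), seed = 11)
  expect_identical(a$sequence, b$sequence)
})

test_that("base and CHC modifications leave the mature duplex region alone", {
  p <- fixture_parent("mir26b")
  core <- function(s, a5, a3) substr(s, a5[1], a3[2])
  sb <- apply_base_modification(p, service = test_service(), seed = 7)
  expect_identical(core(sb$sequence, sb$arm5p, sb$arm3p),
                   core(p$sequence, p$arm5p, p$arm3p))
  sc <- apply_chc_insertion(p, service = test_service(), seed = 7)
  # chc may rewrite only the facing base of the DROSHA site (the core's
  # 3' terminus, the partner of offset 0)
  got <- core(sc$sequence, sc$arm5p, sc$arm3p)
  want <- core(p$sequence, p$arm5p, p$arm3p)
  expect_identical(substr(got, 1, nchar(got) - 1),
                   substr(want, 1, nchar(want) - 1))
})

test_that("loop swap touches only the inter-arm interval", {
  p <- fixture_parent("let7a1")
  s <- apply_loop_swap(p, service = test_service(), seed = 7)
  expect_identical(substr(s$sequence, 1, s$arm5p[2]),
                   substr(p$sequence, 1, p$arm5p[2]))
  expect_identical(substr(s$sequence, s$arm3p[1], nchar(s$sequence)),
                   substr(p$sequence, p$arm3p[1], nchar(p$sequence)))
})

test_that("a parent with arms too close to the sequence end errors", {
  # only 5 nt below the 5p arm: no room for the basal stem and flank
  arm <- "UGAGGUAGUAGGUUGUAUAGUU"
  seq <- paste0("ACGUA", arm, "GCUGUGAAGC", amirna:::rc_rna(arm), "ACACA")
  p <- pri_mirna("thin", seq, c(6, 27), c(38, 59))
  expect_error(apply_base_modification(p, service = test_service(), seed = 1),
               "insufficient 5' context|flank redesign|not a hairpin")
})

test_that("grafting a duplex replaces the arms and re-validates", {
  s <- fixture_all("mir26b")
  g <- screening_guide()
  s2 <- embed_duplex(s, g, service = test_service(), seed = 7)
  expect_identical(s2$guide, g)
  expect_identical(substr(s2$sequence, s2$arm5p[1], s2$arm5p[2]), g)
  expect_identical(s2$passenger, amirna:::rc_rna(g))
  expect_true(all(s2$validation$pass))
})

test_that("grafting the scaffold's own duplex is the identity", {
  s <- fixture_all("mir26b")
  s2 <- embed_duplex(s, s$guide, passenger = s$passenger,
                     service = test_service(), seed = 7)
  expect_identical(s2$sequence, s$sequence)
})

test_that("a duplex that cannot pair fails post-graft validation", {
  s <- fixture_all("mir26b")
  polyA <- strrep("A", 22)
  expect_error(embed_duplex(s, polyA, passenger = polyA,
                            service = test_service(), seed = 7),
               "post-graft validation failed")
})

test_that("guide length outside 18-25 nt is rejected", {
  s <- fixture_all("mir26b")
  expect_error(embed_duplex(s, strrep("ACGU", 8), service = test_service()),
               "18-25")
})

test_that("wild-type parents lack at least one determinant", {
  for (which in c("let7a1", "mir26b")) {
    rep <- validate_scaffold(fixture_parent(which), service = test_service())
    expect_false(all(rep$pass[rep$check %in% c("basal_GU", "chc_bulge")]),
                 label = paste("wild-type", which))
  }
})

test_that("revalidating with a different loop spec fails loop_identity", {
  s <- fixture_all("mir26b")
  other <- modification_spec(loop_sequence = "GGGAAAACCCUUU")
  rep <- validate_scaffold(s, other, service = test_service())
  expect_false(rep$pass[rep$check == "loop_identity"])
  expect_true(all(s$validation$pass))
})

test_that("a failing stage is named in apply_all errors", {
  arm <- "UGAGGUAGUAGGUUGUAUAGUU"
  seq <- paste0("ACGUA", arm, "GCUGUGAAGC", amirna:::rc_rna(arm), "ACACA")
  p <- pri_mirna("thin", seq, c(6, 27), c(38, 59))
  expect_error(apply_all(p, service = test_service(), seed = 1),
               "apply_all stage '")
})

test_that("candidate screening matches a brute-force CNNC scan", {
  set.seed(42)
  spec <- modification_spec()
  cands <- list(); expr <- numeric(0)
  for (k in 1:20) {
    id <- sprintf("cand%02d", k)
    body <- paste0(
      strrep("A", 12),
      "GGGAUGAGGUAGUAGGUUGUAUAGUU", "CUGUGAAGCC",
      "AACUAUACAACCUACUACCUCA")
    flank <- paste(sample(c("A", "G", "U", "C"), 30, replace = TRUE),
                   collapse = "")
    cands[[id]] <- pri_mirna(id, paste0(body, flank),
                             c(13, 34), c(49, 70))
    expr[id] <- sample(0:1000, 1)
  }
  hits <- screen_candidates(expr, cands, top_n = 15, spec = spec)
  # oracle: regex scan of the downstream window
  oracle <- vapply(names(cands), function(id) {
    p <- cands[[id]]
    down <- substr(p$sequence, p$arm3p[2] + 1, nchar(p$sequence))
    win <- substr(down, spec$cnnc_window[1], spec$cnnc_window[2] + 3)
    grepl("C..C", win)
  }, logical(1))
  expect_setequal(hits$id, utils::head(
    names(sort(-expr[names(which(oracle))])), 15))
  expect_lte(nrow(hits), sum(oracle))
})

test_that("screening breaks abundance ties by id and rejects bad input", {
  p <- pri_mirna("x", paste0(strrep("A", 12),
                             "GGGAUGAGGUAGUAGGUUGUAUAGUU", "CUGUGAAGCC",
                             "AACUAUACAACCUACUACCUCA",
                             strrep("A", 16), "CAAC", strrep("A", 10)),
                 c(13, 34), c(49, 70))
  cands <- list(b = p, a = p, c = p)
  cands <- Map(function(q, nm) { q$id <- nm; q }, cands, names(cands))
  hits <- screen_candidates(c(b = 5, a = 5, c = 5), cands)
  expect_identical(hits$id, c("a", "b", "c"))
  expect_error(screen_candidates(numeric(0), cands), "empty")
  expect_error(screen_candidates(c(a = -1), cands), "non-negative")
})
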