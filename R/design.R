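# Scaffold engineering: the four modification classes, the shared
# lower-stem rebuild, and the empirical adjust loop that drives the
# refolded structure to the target geometry.
#
# All operations share one editing representation ("design state"): the
# current sequence plus the tracked mature-arm intervals. Offsets are
# always anchored at the 5p arm start (the putative DROSHA 5' site).

new_design_state <- function(p) {
  if (inherits(p, "EngineeredScaffold")) {
    list(seq = p$sequence, arm5p = p$arm5p, arm3p = p$arm3p,
         id = p$id, parent_id = p$parent_id,
         applied = p$applied_mods, guide_arm = p$guide_arm %||% "5p")
  } else if (inherits(p, "PriMiRNA")) {
    list(seq = p$sequence, arm5p = p$arm5p, arm3p = p$arm3p,
         id = p$id, parent_id = p$id,
         applied = character(0), guide_arm = "5p")
  } else {
    stop("expected a PriMiRNA or EngineeredScaffold", call. = FALSE)
  }
}

st_fold <- function(st, service) {
  fold(st$seq, service, arm5p = st$arm5p, arm3p = st$arm3p, id = st$id)
}

# ---- determinant checks (shared by the engine and validate_scaffold) ----

check_basal_gu <- function(fh, spec) {
  a <- fh$anchor
  if (a < 15L) {
    return(list(ok = FALSE, msg = "fewer than 14 nt 5' of the mature arm"))
  }
  got <- substr(fh$sequence, a - 14L, a - 13L)
  list(ok = got == spec$basal_dinucleotide,
       msg = sprintf("offsets -14/-13 carry %s (want %s)", got,
                     spec$basal_dinucleotide))
}

check_chc <- function(fh, spec) {
  o <- spec$chc_offset
  pt <- fh$pair_table
  i_lo <- fh$anchor + o       # 5' position at chc_offset
  i_hi <- fh$anchor + o + 1L  # one step toward the DROSHA site
  if (i_lo < 1L || is.na(pt[i_lo]) || is.na(pt[i_hi])) {
    return(list(ok = FALSE,
                msg = sprintf("offsets %d/%d not both paired", o, o + 1L)))
  }
  j_hi <- pt[i_hi]  # partner of offset o+1 (5'-most of the two on 3' strand)
  j_lo <- pt[i_lo]
  if (j_lo - j_hi != 2L) {
    return(list(ok = FALSE,
                msg = sprintf("no single-nt 3'-strand bulge between partners of %d and %d",
                              o + 1L, o)))
  }
  b <- j_hi + 1L
  h <- substr(fh$sequence, b, b)
  ctx <- c(substr(fh$sequence, j_hi, j_hi), substr(fh$sequence, j_lo, j_lo))
  ok <- is.na(pt[b]) && h %in% c("A", "C", "U") && all(ctx == "C")
  list(ok = ok,
       msg = sprintf("bulge context %s-%s-%s at 3'-strand position %d",
                     ctx[1], h, ctx[2], b))
}

check_debulged <- function(fh, spec) {
  w <- spec$debulge_window
  pt <- fh$pair_table
  offs <- seq(w[2], w[1])  # high to low, e.g. 0 .. -13
  idx <- fh$anchor + offs
  if (any(idx < 1L)) {
    return(list(ok = FALSE, msg = "window extends beyond the sequence"))
  }
  unpaired <- offs[is.na(pt[idx])]
  if (length(unpaired)) {
    return(list(ok = FALSE,
                msg = paste("unpaired window offsets:",
                            paste(unpaired, collapse = " "))))
  }
  j <- pt[idx]
  d <- diff(j)  # partner step as offset decreases by 1
  allowed <- rep(1L, length(d))
  # the single CHC bulge between the partners of chc_offset+1 and chc_offset
  gap_at <- which(offs[-1] == spec$chc_offset)
  if (length(gap_at)) allowed[gap_at] <- 2L
  bad <- which(d != 1L & d != allowed)
  if (length(bad)) {
    return(list(ok = FALSE,
                msg = paste("bulge/internal loop at window offsets:",
                            paste(offs[bad + 1L], collapse = " "))))
  }
  list(ok = TRUE, msg = "window bulge-free")
}

check_stem_len <- function(fh, spec) {
  n <- tryCatch(stem_pairs(fh)$n_pairs, error = function(e) NA_integer_)
  list(ok = !is.na(n) && n == spec$stem_len_target,
       msg = sprintf("stem has %s pairs (target %d)",
                     ifelse(is.na(n), "?", n), spec$stem_len_target))
}

check_loop <- function(fh, spec) {
  ins <- c(fh$arm5p[2] + 1L, fh$arm3p[1] - 1L)
  got <- substr(fh$sequence, ins[1], ins[2])
  if (got != spec$loop_sequence) {
    return(list(ok = FALSE,
                msg = sprintf("inter-arm loop is %s (want %s)", got,
                              spec$loop_sequence)))
  }
  inside <- !is.null(fh$loop) && fh$loop[1] >= ins[1] && fh$loop[2] <= ins[2]
  list(ok = inside, msg = "terminal loop lies within the configured loop")
}

check_flanks <- function(fh, spec) {
  sp <- tryCatch(stem_pairs(fh), error = function(e) NULL)
  if (is.null(sp) || sp$n_pairs == 0L) {
    return(list(ok = FALSE, msg = "no stem to flank"))
  }
  fl <- spec$flank_unstructured_len
  i0 <- sp$pairs$i[1]; j0 <- sp$pairs$j[nrow(sp$pairs)]
  # basal-most pair: smallest i, largest j
  i0 <- min(sp$pairs$i); j0 <- max(sp$pairs$j)
  pt <- fh$pair_table
  left <- seq.int(max(1L, i0 - fl), i0 - 1L)
  right <- seq.int(j0 + 1L, min(length(pt), j0 + fl))
  bad <- c(left[!is.na(pt[left])], right[!is.na(pt[right])])
  list(ok = length(bad) == 0L,
       msg = if (length(bad)) {
           paste("paired flank positions:", paste(bad, collapse = " "))
         } else "flanks unpaired")
}

scaffold_checks <- function(fh, spec) {
  list(
    basal_GU = check_basal_gu(fh, spec),
    chc_bulge = check_chc(fh, spec),
    debulged_window = check_debulged(fh, spec),
    stem_length = check_stem_len(fh, spec),
    loop_identity = check_loop(fh, spec),
    flanks_unstructured = check_flanks(fh, spec),
    single_hairpin = list(ok = TRUE, msg = "single terminal loop between arms")
  )
}

CHECKS_BY_MOD <- list(
  base = c("basal_GU", "stem_length", "flanks_unstructured"),
  chc = c("chc_bulge", "debulged_window"),
  loop = c("loop_identity")
)

# ---- lower-stem rebuild -------------------------------------------------

# Rebuild everything below the mature duplex: sampled unstructured flanks,
# an optional Watson-Crick extension helix, the 14 basal 5'-strand bases
# (parent bases, with the basal dinucleotide and/or the CHC G/G context
# written in), and a freshly written 3' lower strand pairing the top k
# basal offsets. Positions at and above the 5p arm start, through the 3p
# arm end, are untouched.
rebuild_lower <- function(st, spec, k, ext, ext_seq, flank5, flank3,
                          gu = FALSE, chc = FALSE) {
  a <- st$arm5p[1]
  if (a - 1L < 14L) {
    stop("insufficient 5' context: need 14 nt below the mature arm",
         call. = FALSE)
  }
  b <- substr(st$seq, a - 14L, a - 1L)  # offsets -14 .. -1
  if (gu) {
    substr(b, 1L, 2L) <- spec$basal_dinucleotide
  }
  if (chc) {
    if (spec$chc_offset > -2L) {
      stop("chc_offset must be <= -2 so the C-H-C context sits below the ",
           "DROSHA site", call. = FALSE)
    }
    # paired G/G context at chc_offset and chc_offset+1 (b index 15+offset)
    substr(b, 15L + spec$chc_offset, 15L + spec$chc_offset) <- "G"
    substr(b, 16L + spec$chc_offset, 16L + spec$chc_offset) <- "G"
  }
  core <- substr(st$seq, a, st$arm3p[2])
  if (chc && spec$debulge_window[2] >= 0L) {
    # the window reaches the DROSHA site: pair offset 0 with its facing
    # base, the core's 3' terminus (blunt lower-duplex geometry)
    want <- RNA_COMPLEMENT[[substr(core, 1L, 1L)]]
    substr(core, nchar(core), nchar(core)) <- want
  }
  bb <- strsplit(b, "")[[1]]
  # 3' lower strand, 5'->3': partner of -1 first, down to partner of -k
  lower3 <- character(0)
  if (k > 0L) {
    lower3 <- unname(RNA_COMPLEMENT[bb[15L - seq_len(k)]])
    if (chc && k >= -spec$chc_offset) {
      at <- -spec$chc_offset - 1L  # after the partner of chc_offset+1
      lower3 <- append(lower3, spec$chc_bulge_nt, after = at)
    }
  }
  ext3 <- if (ext > 0L) rc_rna(ext_seq) else ""
  seq <- paste0(flank5, ext_seq, b, core, paste(lower3, collapse = ""),
                ext3, flank3)
  if (nchar(seq) > spec$max_pri_len) {
    stop("stem redesign failed: length budget of ", spec$max_pri_len,
         " nt exceeded", call. = FALSE)
  }
  shift <- (nchar(flank5) + nchar(ext_seq) + 14L + 1L) - a
  st$seq <- seq
  st$arm5p <- st$arm5p + shift
  st$arm3p <- st$arm3p + shift
  st
}

# Adjust loop: iterate (k, ext) and flank resampling until the refolded
# scaffold hits the stem-pair target, keeps the configured flanks unpaired
# and (when requested) carries the CHC bulge in a bulge-free window.
# Sampling is driven by the caller's seeded RNG stream.
ensure_geometry <- function(st, spec, service, gu = FALSE, chc = FALSE,
                            stem = TRUE) {
  fl <- spec$flank_unstructured_len
  flank5 <- sample_rna(fl, c("A", "C"))
  flank3 <- sample_rna(fl, c("A", "C"))
  k <- 13L; ext <- 0L; ext_seq <- ""
  last_sig <- ""
  for (attempt in seq_len(spec$max_attempts)) {
    if (nchar(ext_seq) != ext) ext_seq <- sample_rna(ext)
    st2 <- rebuild_lower(st, spec, k, ext, ext_seq, flank5, flank3,
                         gu = gu, chc = chc)
    fh <- tryCatch(st_fold(st2, service), error = function(e) e)
    if (inherits(fh, "error")) {
      # branched refold: reshuffle the sampled components and retry
      flank5 <- sample_rna(fl, c("A", "C"))
      flank3 <- sample_rna(fl, c("A", "C"))
      if (ext > 0L) ext_seq <- sample_rna(ext)
      next
    }
    if (stem) {
      n <- stem_pairs(fh)$n_pairs
      if (n != spec$stem_len_target) {
        sig <- paste(k, ext, n)
        if (identical(sig, last_sig)) {
          # same geometry, same miss: reshuffle to escape the cycle
          if (ext > 0L) ext_seq <- sample_rna(ext)
          flank5 <- sample_rna(fl, c("A", "C"))
          last_sig <- ""
          next
        }
        last_sig <- sig
        delta <- spec$stem_len_target - n
        if (delta > 0L) {
          if (k < 13L) {
            k <- min(13L, k + delta)
          } else {
            ext <- ext + delta
          }
        } else {
          take <- min(ext, -delta)
          ext <- ext - take
          k <- max(0L, k - (-delta - take))
        }
        next
      }
    }
    if (chc) {
      okc <- check_chc(fh, spec)$ok && check_debulged(fh, spec)$ok
      if (!okc) {
        flank3 <- sample_rna(fl, c("A", "C"))
        if (ext > 0L) ext_seq <- sample_rna(ext)
        next
      }
    }
    fk <- check_flanks(fh, spec)
    if (!fk$ok) {
      flank5 <- sample_rna(fl, c("A", "C"))
      flank3 <- sample_rna(fl, c("A", "C"))
      next
    }
    return(st2)
  }
  stop(if (stem) "stem redesign failed" else "flank redesign failed",
       ": no valid geometry within ", spec$max_attempts, " attempts",
       call. = FALSE)
}

# ---- scaffold object ----------------------------------------------------

as_scaffold <- function(st, spec, service, applied, label = NULL) {
  fh <- st_fold(st, service)
  checks <- scaffold_checks(fh, spec)
  rep <- validation_report_from_checks(checks)
  id <- if (!is.null(label)) paste0(st$parent_id, "_", label) else st$id
  garm <- st$guide_arm %||% "5p"
  guide <- substr_interval(st$seq, if (garm == "5p") st$arm5p else st$arm3p)
  pass <- substr_interval(st$seq, if (garm == "5p") st$arm3p else st$arm5p)
  structure(
    list(id = id, parent_id = st$parent_id, sequence = st$seq,
         structure = fh$structure, applied_mods = applied,
         guide = guide, passenger = pass, guide_arm = garm,
         arm5p = st$arm5p, arm3p = st$arm3p, anchor = st$arm5p[1],
         spec = spec, validation = rep),
    class = "EngineeredScaffold"
  )
}

#' @export
print.EngineeredScaffold <- function(x, ...) {
  cat("EngineeredScaffold", x$id, "(", nchar(x$sequence), "nt )\n")
  cat("  parent:", x$parent_id, " mods:",
      if (length(x$applied_mods)) paste(x$applied_mods, collapse = "+") else "none",
      "\n")
  cat(" ", x$sequence, "\n")
  cat(" ", x$structure, "\n")
  cat("  guide (", x$guide_arm, "):", x$guide, "\n")
  ok <- x$validation$pass
  cat("  validation:", if (all(ok)) "PASS" else
    paste("FAIL:", paste(x$validation$check[!ok], collapse = ", ")), "\n")
  invisible(x)
}

#' Convert an engineered scaffold back to an annotated pri-miRNA
#'
#' Useful for re-applying modifications (idempotence) or for feeding a
#' scaffold through parent-oriented entry points.
#' @param s An `EngineeredScaffold`.
#' @export
as_pri_mirna <- function(s) {
  stopifnot(inherits(s, "EngineeredScaffold"))
  pri_mirna(s$id, s$sequence, s$arm5p, s$arm3p,
            max_len = s$spec$max_pri_len %||% 200L)
}

required_pass <- function(scaffold, mods) {
  need <- c(unlist(CHECKS_BY_MOD[mods], use.names = FALSE), "single_hairpin")
  rep <- scaffold$validation
  bad <- rep$check[rep$check %in% need & !rep$pass]
  if (length(bad)) {
    stop("validation failed for checks: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(scaffold)
}

fastpath <- function(st, spec, service, mods) {
  fh <- tryCatch(st_fold(st, service), error = function(e) NULL)
  if (is.null(fh)) return(NULL)
  checks <- scaffold_checks(fh, spec)
  need <- unlist(CHECKS_BY_MOD[mods], use.names = FALSE)
  if (all(vapply(checks[need], `[[`, logical(1), "ok"))) fh else NULL
}

# ---- the four modification operations -----------------------------------

#' Apply the base-of-stem modification
#'
#' Writes the basal dinucleotide (default `GU`) at offsets -14/-13,
#' rebuilds the basal stem so the refolded scaffold has exactly the target
#' number of stem pairs (default 35: extension pairs are appended below the
#' basal end, or basal pairs dropped, as needed), and resamples the
#' flanking sequence until the configured number of nucleotides beyond the
#' stem refolds unpaired on both sides. An input that already satisfies
#' these three determinants is returned unchanged (the operation is a fixed
#' point on its own output).
#'
#' @param p A [pri_mirna()] or `EngineeredScaffold`.
#' @param spec A [modification_spec()].
#' @param service A folding service ([rnafold_service()] by default).
#' @param seed Integer seed driving the bounded resampling.
#' @return An `EngineeredScaffold`.
#' @export
apply_base_modification <- function(p, spec = modification_spec(),
                                    service = rnafold_service(), seed = 1L) {
  st <- new_design_state(p)
  st_fold(st, service)  # precondition: parent folds as a single hairpin
  with_rng(seed, {
    if (!is.null(fastpath(st, spec, service, "base"))) {
      s <- as_scaffold(st, spec, service,
                       applied = union(st$applied, "base"), label = NULL)
    } else {
      st2 <- ensure_geometry(st, spec, service, gu = TRUE,
                             chc = "chc" %in% st$applied, stem = TRUE)
      s <- as_scaffold(st2, spec, service,
                       applied = union(st$applied, "base"), label = "base")
    }
    required_pass(s, "base")
  })
}

#' Apply the CHC insertion
#'
#' Removes all bulges in the debulge window (default offsets -13 to 0) by
#' rewriting the 3' lower strand as the Watson-Crick complement of the
#' basal 5' strand, and inserts the single-nucleotide C-H-C bulge: the
#' bulged H sits on the 3' strand between the partners of `chc_offset` and
#' `chc_offset + 1`, with the paired C/C context facing G/G on the 5'
#' strand. An input already carrying the bulge in a bulge-free window is
#' returned unchanged.
#'
#' @inheritParams apply_base_modification
#' @return An `EngineeredScaffold`.
#' @export
apply_chc_insertion <- function(p, spec = modification_spec(),
                                service = rnafold_service(), seed = 1L) {
  st <- new_design_state(p)
  st_fold(st, service)
  with_rng(seed, {
    if (!is.null(fastpath(st, spec, service, "chc"))) {
      s <- as_scaffold(st, spec, service,
                       applied = union(st$applied, "chc"), label = NULL)
    } else {
      st2 <- ensure_geometry(st, spec, service,
                             gu = "base" %in% st$applied, chc = TRUE,
                             stem = "base" %in% st$applied)
      s <- as_scaffold(st2, spec, service,
                       applied = union(st$applied, "chc"), label = "chc")
    }
    required_pass(s, "chc")
  })
}

#' Replace the terminal loop
#'
#' Replaces the region between the mature arms with the configured loop
#' (the miR-30a loop by default). The refolded scaffold must keep its
#' single-hairpin topology with the terminal loop inside the new insert;
#' otherwise a "loop swap destabilized hairpin" error is raised. When the
#' parent's inter-arm region already equals the configured loop the input
#' is returned unchanged.
#'
#' @inheritParams apply_base_modification
#' @return An `EngineeredScaffold`.
#' @export
apply_loop_swap <- function(p, spec = modification_spec(),
                            service = rnafold_service(), seed = 1L) {
  st <- new_design_state(p)
  st_fold(st, service)  # identifiable terminal loop required
  ins <- c(st$arm5p[2] + 1L, st$arm3p[1] - 1L)
  current <- substr(st$seq, ins[1], ins[2])
  changed <- current != spec$loop_sequence
  if (changed) {
    st$seq <- paste0(substr(st$seq, 1L, ins[1] - 1L), spec$loop_sequence,
                     substr(st$seq, ins[2] + 1L, nchar(st$seq)))
    st$arm3p <- st$arm3p + (nchar(spec$loop_sequence) - nchar(current))
    if (nchar(st$seq) > spec$max_pri_len) {
      stop("loop swap exceeds the length budget", call. = FALSE)
    }
  }
  fh <- tryCatch(st_fold(st, service), error = function(e) e)
  if (inherits(fh, "error") || !check_loop(fh, spec)$ok) {
    stop("loop swap destabilized hairpin", call. = FALSE)
  }
  s <- as_scaffold(st, spec, service, applied = union(st$applied, "loop"),
                   label = if (changed) "loop" else NULL)
  required_pass(s, "loop")
}

#' Apply all modifications
#'
#' Composes base-of-stem, CHC insertion and loop replacement (in that
#' order, refolding between stages), then re-enforces the stem-pair target
#' after the loop swap and validates every determinant. A stage failure
#' propagates with the stage name; the returned scaffold's validation
#' report passes all seven checks.
#'
#' @inheritParams apply_base_modification
#' @return An `EngineeredScaffold` whose validation fully passes.
#' @export
apply_all <- function(p, spec = modification_spec(),
                      service = rnafold_service(), seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("apply_all stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  s <- stage("base", apply_base_modification(p, spec, service, seed))
  s <- stage("chc", apply_chc_insertion(s, spec, service, seed + 1L))
  s <- stage("loop", apply_loop_swap(s, spec, service, seed + 2L))
  # the loop swap changes the pair budget above the DROSHA site;
  # re-enforce the stem target with the CHC bulge in place
  st <- new_design_state(s)
  s2 <- with_rng(seed + 3L, {
    if (is.null(fastpath(st, spec, service, c("base", "chc", "loop")))) {
      st <- ensure_geometry(st, spec, service, gu = TRUE, chc = TRUE,
                            stem = TRUE)
    }
    as_scaffold(st, spec, service, applied = c("base", "chc", "loop"),
                label = NULL)
  })
  s2$id <- paste0(s2$parent_id, "_all")
  if (!all(s2$validation$pass)) {
    stop("apply_all stage 'final validation': checks failed: ",
         paste(s2$validation$check[!s2$validation$pass], collapse = ", "),
         call. = FALSE)
  }
  s2
}

#' Graft a guide/passenger duplex into a scaffold
#'
#' Replaces the mature duplex with the supplied guide (and passenger; the
#' full reverse complement when omitted), leaving all scaffold sequence
#' outside the duplex untouched, then re-enforces the geometry implied by
#' the scaffold's applied modifications and re-validates. A graft that
#' breaks a determinant carried by the scaffold raises a "post-graft
#' validation failed" error listing the failing checks.
#'
#' @param s An `EngineeredScaffold` (or a [pri_mirna()], treated as an
#'   unmodified scaffold).
#' @param guide Guide strand, 18-25 nt, written 5' to 3'.
#' @param passenger Optional passenger strand; defaults to the full
#'   reverse complement of the guide.
#' @param guide_arm Arm carrying the guide, `"5p"` (default) or `"3p"`.
#' @inheritParams apply_base_modification
#' @return An `EngineeredScaffold` with the new duplex.
#' @export
embed_duplex <- function(s, guide, passenger = NULL, guide_arm = c("5p", "3p"),
                         spec = NULL, service = rnafold_service(), seed = 1L) {
  guide_arm <- match.arg(guide_arm)
  guide <- as_rna(guide, "guide")
  if (nchar(guide) < 18L || nchar(guide) > 25L) {
    stop("guide must be 18-25 nt", call. = FALSE)
  }
  passenger <- if (is.null(passenger)) rc_rna(guide) else
    as_rna(passenger, "passenger")
  st <- new_design_state(s)
  spec <- spec %||% (if (inherits(s, "EngineeredScaffold")) s$spec else
    modification_spec())
  st$guide_arm <- guide_arm
  arm5_new <- if (guide_arm == "5p") guide else passenger
  arm3_new <- if (guide_arm == "5p") passenger else guide
  same <- identical(substr_interval(st$seq, st$arm5p), arm5_new) &&
    identical(substr_interval(st$seq, st$arm3p), arm3_new)
  if (!same) {
    n <- nchar(st$seq)
    d5 <- nchar(arm5_new) - (st$arm5p[2] - st$arm5p[1] + 1L)
    seq <- paste0(substr(st$seq, 1L, st$arm5p[1] - 1L), arm5_new,
                  substr(st$seq, st$arm5p[2] + 1L, st$arm3p[1] - 1L),
                  arm3_new,
                  substr(st$seq, st$arm3p[2] + 1L, n))
    st$arm5p <- c(st$arm5p[1], st$arm5p[1] + nchar(arm5_new) - 1L)
    st$arm3p <- c(st$arm3p[1] + d5,
                  st$arm3p[1] + d5 + nchar(arm3_new) - 1L)
    st$seq <- seq
  }
  out <- tryCatch({
    with_rng(seed, {
      if ("base" %in% st$applied || "chc" %in% st$applied) {
        if (is.null(fastpath(st, spec, service, st$applied))) {
          st <- ensure_geometry(st, spec, service,
                                gu = "base" %in% st$applied,
                                chc = "chc" %in% st$applied,
                                stem = "base" %in% st$applied)
        }
      }
      sc <- as_scaffold(st, spec, service, applied = st$applied, label = NULL)
      if (length(st$applied)) required_pass(sc, st$applied)
      sc
    })
  }, error = function(e) {
    stop("post-graft validation failed: ", conditionMessage(e), call. = FALSE)
  })
  out
}

#' Validate a scaffold against the processing determinants
#'
#' Refolds the scaffold and checks each determinant: basal dinucleotide at
#' -14/-13, CHC bulge, bulge-free window, stem-pair count, loop identity,
#' unstructured flanks and single-hairpin topology. Report-based: never
#' raises on a failing determinant.
#'
#' @param s An `EngineeredScaffold` or [pri_mirna()].
#' @param spec A [modification_spec()]; defaults to the scaffold's own.
#' @param service A folding service.
#' @return A `ValidationReport` data.frame (`check`, `pass`, `message`)
#'   with attribute `pass` (TRUE iff every check passes).
#' @export
validate_scaffold <- function(s, spec = NULL, service = rnafold_service()) {
  spec <- spec %||% (if (inherits(s, "EngineeredScaffold")) s$spec else
    modification_spec())
  st <- new_design_state(s)
  fh <- tryCatch(st_fold(st, service), error = function(e) e)
  if (inherits(fh, "error")) {
    checks <- lapply(stats::setNames(nm = names(scaffold_checks_empty())),
                     function(nm) list(ok = FALSE,
                                       msg = conditionMessage(fh)))
    return(validation_report_from_checks(checks))
  }
  validation_report_from_checks(scaffold_checks(fh, spec))
}

scaffold_checks_empty <- function() {
  c(basal_GU = NA, chc_bulge = NA, debulged_window = NA, stem_length = NA,
    loop_identity = NA, flanks_unstructured = NA, single_hairpin = NA)
}

validation_report_from_checks <- function(checks) {
  rep <- data.frame(
    check = names(checks),
    pass = vapply(checks, `[[`, logical(1), "ok"),
    message = vapply(checks, `[[`, character(1), "msg"),
    row.names = NULL
  )
  class(rep) <- c("ValidationReport", "data.frame")
  attr(rep, "pass") <- all(rep$pass)
  rep
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport:", if (attr(x, "pass")) "PASS" else "FAIL", "\n")
  for (k in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-20s %s\n", if (x$pass[k]) "ok" else "XX",
                x$check[k], if (x$pass[k]) "" else x$message[k]))
  }
  invisible(x)
}
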