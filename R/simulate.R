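# Seeded small-RNA read simulator: the ground-truth generator that makes
# the quantification pipeline testable without sequencing data.

#' Simulation configuration
#'
#' Describes the processing statistics the simulator emulates: library
#' size, the guide:passenger loading bias, and independent 5'/3'
#' cleavage-site jitter distributions over offset shifts of -2..+2
#' nucleotides. The default `guide_fraction` of 0.998 corresponds to the
#' ~500:1 strand bias of a well-processed scaffold; the default jitter is
#' a point mass at 0 (perfectly homogeneous ends).
#'
#' @param n_reads Number of reads to simulate.
#' @param guide_fraction Probability a read comes from the guide strand.
#' @param start_jitter,end_jitter Named numeric vectors of probabilities
#'   over shifts (names in `-2..2`), each summing to 1.
#' @param min_len,max_len Accepted read-length band used for clamping.
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A `SimulationConfig` object.
#' @export
simulation_config <- function(n_reads = 10000L, guide_fraction = 0.998,
                              start_jitter = c("0" = 1),
                              end_jitter = c("0" = 1),
                              min_len = 18L, max_len = 24L, seed = 1L) {
  chk_jitter <- function(j, what) {
    if (is.null(names(j)) || anyNA(suppressWarnings(as.integer(names(j))))) {
      stop(what, " must be a named vector of probabilities keyed by shift",
           call. = FALSE)
    }
    sh <- as.integer(names(j))
    if (any(sh < -2L | sh > 2L)) {
      stop(what, " shifts must lie in -2..2", call. = FALSE)
    }
    if (any(j < 0) || abs(sum(j) - 1) > 1e-9) {
      stop(what, " probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
    stats::setNames(as.numeric(j), sh)
  }
  if (guide_fraction < 0 || guide_fraction > 1) {
    stop("guide_fraction must be a probability", call. = FALSE)
  }
  structure(
    list(n_reads = as.integer(n_reads), guide_fraction = guide_fraction,
         start_jitter = chk_jitter(start_jitter, "start_jitter"),
         end_jitter = chk_jitter(end_jitter, "end_jitter"),
         min_len = as.integer(min_len), max_len = as.integer(max_len),
         seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

draw_shifts <- function(j, n) {
  as.integer(sample(names(j), n, replace = TRUE, prob = j))
}

#' Simulate small-RNA reads from an engineered scaffold
#'
#' Draws each read's strand (guide with probability `guide_fraction`),
#' 5' and 3' cleavage shifts, and emits the exact window substring at the
#' jittered coordinates. Reads whose jittered length leaves the permitted
#' band (or the window) are resampled, with a hard cap on resampling.
#' Alongside the read set, the simulator returns per-read ground truth and
#' the aggregate truth (true guide:passenger ratio and true 5' fidelity
#' among guide reads), and optionally writes FASTQ plus a pre-made SAM
#' against the reference windows, so downstream stages can be exercised
#' with or without an aligner.
#'
#' @param s An `EngineeredScaffold`.
#' @param cfg A [simulation_config()].
#' @param flank_len Window flank length (default 10).
#' @param out_prefix When non-`NULL`, writes `<prefix>.fastq`,
#'   `<prefix>.sam`, `<prefix>_truth.tsv` and `<prefix>_truth.json`.
#' @return List with `reads` (data.frame in the [read_alignments()]
#'   layout), `windows`, `truth` (per-read data.frame) and `truth_summary`
#'   (`true_ratio`, `true_fidelity`, counts; `NA`-flagged when
#'   `n_reads = 0`).
#' @export
simulate_reads <- function(s, cfg = simulation_config(), flank_len = 10L,
                           out_prefix = NULL) {
  windows <- build_reference_windows(s, flank_len = flank_len)
  max_resample <- 100L
  gen <- function() {
    n <- cfg$n_reads
    role <- ifelse(stats::runif(n) < cfg$guide_fraction, "guide", "passenger")
    s_shift <- draw_shifts(cfg$start_jitter, n)
    e_shift <- draw_shifts(cfg$end_jitter, n)
    for (tries in seq_len(max_resample)) {
      w_len <- ifelse(role == "guide", nchar(windows$guide$window),
                      nchar(windows$passenger$window))
      c_start <- ifelse(role == "guide", windows$guide$core_start,
                        windows$passenger$core_start)
      c_end <- ifelse(role == "guide", windows$guide$core_end,
                      windows$passenger$core_end)
      start <- c_start + s_shift
      end <- c_end + e_shift
      len <- end - start + 1L
      bad <- start < 1L | end > w_len | len < cfg$min_len | len > cfg$max_len
      if (!any(bad)) break
      if (tries == max_resample) {
        stop("read resampling cap exceeded: jitter incompatible with the ",
             "length band", call. = FALSE)
      }
      s_shift[bad] <- draw_shifts(cfg$start_jitter, sum(bad))
      e_shift[bad] <- draw_shifts(cfg$end_jitter, sum(bad))
    }
    list(role = role, s_shift = s_shift, e_shift = e_shift,
         start = start, end = end, len = len)
  }
  if (cfg$n_reads == 0L) {
    reads <- data.frame(qname = character(0), flag = integer(0),
                        window = character(0), pos = integer(0),
                        cigar = character(0), seq = character(0))
    truth <- data.frame(qname = character(0), role = character(0),
                        start_shift = integer(0), end_shift = integer(0))
    summary <- list(n_guide = 0L, n_passenger = 0L, true_ratio = NA_real_,
                    true_fidelity = NA_real_, defined = FALSE)
  } else {
    d <- with_rng(cfg$seed, gen())
    win <- ifelse(d$role == "guide", windows$guide$id, windows$passenger$id)
    wseq <- ifelse(d$role == "guide", toupper(as_dna(windows$guide$window)),
                   toupper(as_dna(windows$passenger$window)))
    reads <- data.frame(
      qname = sprintf("read%06d", seq_len(cfg$n_reads)),
      flag = 0L, window = win, pos = d$start,
      cigar = paste0(d$len, "M"),
      seq = substr(wseq, d$start, d$end),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(qname = reads$qname, role = d$role,
                        start_shift = d$s_shift, end_shift = d$e_shift)
    ng <- sum(d$role == "guide"); np <- cfg$n_reads - ng
    summary <- list(
      n_guide = ng, n_passenger = np,
      true_ratio = if (np > 0L) ng / np else if (ng > 0L) Inf else NA_real_,
      true_fidelity = if (ng > 0L) {
          100 * sum(d$s_shift == 0L & d$role == "guide") / ng
        } else NA_real_,
      defined = cfg$n_reads > 0L
    )
  }
  out <- list(reads = reads, windows = windows, truth = truth,
              truth_summary = summary)
  if (!is.null(out_prefix)) {
    write_fastq(reads, paste0(out_prefix, ".fastq"))
    write_sam(reads, windows, paste0(out_prefix, ".sam"))
    utils::write.table(truth, paste0(out_prefix, "_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, paste0(out_prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paste0(out_prefix, c(".fastq", ".sam", "_truth.tsv",
                                      "_truth.json"))
  }
  out
}

#' Write simulated reads as FASTQ
#'
#' Four-line records with a constant high base quality (quality modelling
#' is outside the simulator's scope).
#' @param reads data.frame with `qname` and `seq`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  if (!nrow(reads)) { writeLines(character(0), path); return(invisible(path)) }
  rec <- rbind(paste0("@", reads$qname),
               reads$seq,
               "+",
               vapply(nchar(reads$seq), function(n) strrep("I", n),
                      character(1)))
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Write read records as SAM against the reference windows
#'
#' Emits `@SQ` headers naming each window and one forward-strand primary
#' record per read with a pure-match CIGAR.
#' @param reads data.frame in the [read_alignments()] layout.
#' @param windows List of `ReferenceWindow` objects.
#' @param path Output path.
#' @export
write_sam <- function(reads, windows, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           vapply(windows, function(w) {
             sprintf("@SQ\tSN:%s\tLN:%d", w$id, nchar(w$window))
           }, character(1)))
  body <- if (nrow(reads)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            reads$qname, reads$flag, reads$window, reads$pos, 60L,
            reads$cigar, reads$seq,
            vapply(nchar(reads$seq), function(n) strrep("I", n), character(1)))
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
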