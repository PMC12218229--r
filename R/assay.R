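# Closed-form calculators for the non-sequencing readouts: reporter-assay
# knockdown normalization and 2D-ddPCR genome-integrity fraction.

#' Residual reporter expression from flow-cytometry medians
#'
#' Normalizes the mCherry median fluorescence of transduced (GFP+) cells
#' over non-transduced (GFP-) cells within the same sample:
#' `ratio = median(GFP+) / median(GFP-)`. A ratio of 1 means no silencing;
#' the complementary knockdown percentage `100 * (1 - ratio)` is reported
#' alongside. The ratio is scale-invariant in the fluorescence units.
#'
#' @param mcherry_gfp_pos,mcherry_gfp_neg Median mCherry fluorescence of
#'   the GFP+ and GFP- populations (same arbitrary units); vectorized.
#' @param id Optional sample ids.
#' @return data.frame with `id`, `ratio` and `knockdown_pct`.
#' @examples
#' residual_expression(30, 100)  # ratio 0.30, 70% knockdown
#' @export
residual_expression <- function(mcherry_gfp_pos, mcherry_gfp_neg, id = NULL) {
  if (any(mcherry_gfp_pos < 0) || any(mcherry_gfp_neg < 0)) {
    stop("fluorescence medians must be non-negative", call. = FALSE)
  }
  if (any(mcherry_gfp_neg <= 0)) {
    stop("GFP- median must be positive (denominator)", call. = FALSE)
  }
  ratio <- mcherry_gfp_pos / mcherry_gfp_neg
  data.frame(id = id %||% seq_along(ratio), ratio = ratio,
             knockdown_pct = 100 * (1 - ratio))
}

#' Percent intact vector genomes from 2D-ddPCR droplet counts
#'
#' Fraction of droplets PCR-positive for probes at both cassette ends
#' (e.g. the CMV enhancer and the hGH polyA) within the same droplet -- a
#' proxy for physically intact vector genomes. By default the denominator
#' is all probe-positive droplets (double plus single positives); setting
#' `denominator = "all"` includes negative droplets as well. No
#' Poisson copies-per-droplet correction is applied: this is a plain
#' droplet-fraction calculation.
#'
#' @param double_positive,cmv_only,polya_only,negative Droplet counts;
#'   vectorized.
#' @param denominator `"positives"` (default) or `"all"`.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' intact_genome_percent(900, 50, 50, 9000)  # 90
#' @export
intact_genome_percent <- function(double_positive, cmv_only, polya_only,
                                  negative = 0,
                                  denominator = c("positives", "all")) {
  denominator <- match.arg(denominator)
  counts <- cbind(double_positive, cmv_only, polya_only, negative)
  if (any(counts < 0)) stop("droplet counts must be non-negative",
                            call. = FALSE)
  pos <- double_positive + cmv_only + polya_only
  if (any(pos == 0)) {
    stop("no probe-positive droplets: intact percentage undefined",
         call. = FALSE)
  }
  den <- if (denominator == "all") pos + negative else pos
  100 * double_positive / den
}

#' Reporter-assay table calculator
#'
#' Applies [residual_expression()] to a TSV with columns `id`,
#' `mcherry_gfp_pos`, `mcherry_gfp_neg`.
#' @param path Input TSV.
#' @return data.frame of results.
#' @export
reporter_assay_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "mcherry_gfp_pos", "mcherry_gfp_neg")
  if (!all(need %in% names(tab))) {
    stop("reporter TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  residual_expression(tab$mcherry_gfp_pos, tab$mcherry_gfp_neg, id = tab$id)
}

#' 2D-ddPCR table calculator
#'
#' Applies [intact_genome_percent()] to a TSV with columns `id`,
#' `double_positive`, `cmv_only`, `polya_only` and optionally `negative`.
#' @param path Input TSV.
#' @param denominator Passed to [intact_genome_percent()].
#' @return data.frame with `id` and `intact_pct`.
#' @export
ddpcr_table <- function(path, denominator = c("positives", "all")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "double_positive", "cmv_only", "polya_only")
  if (!all(need %in% names(tab))) {
    stop("ddPCR TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  neg <- if ("negative" %in% names(tab)) tab$negative else 0
  data.frame(id = tab$id,
             intact_pct = intact_genome_percent(
               tab$double_positive, tab$cmv_only, tab$polya_only, neg,
               denominator = denominator))
}
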