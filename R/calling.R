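CALL_LEVELS <- c("HOMDEL", "LOSS", "NEUTRAL", "GAIN", "AMP")

#' Classify segments into copy-number states
#'
#' Applies the study's printed extreme thresholds — amplification for a
#' segment mean log2 ratio above `amp_thr` (+1.5), homozygous deletion below
#' `homdel_thr` (-1.5) — and conventional gain/loss cutoffs for single-copy
#' changes in between. Calls are ordered
#' `HOMDEL < LOSS < NEUTRAL < GAIN < AMP` and are monotone in the segment
#' mean.
#'
#' @param segments data.frame of segments (see [cbs_segment()]).
#' @param gain_thr,loss_thr Single-copy thresholds (defaults +0.2 / -0.2
#'   log2 units); must satisfy `loss_thr < 0 < gain_thr < amp_thr`.
#' @param amp_thr,homdel_thr Extreme thresholds (defaults +1.5 / -1.5).
#' @return The segments with an added `call` column.
#' @export
call_segments <- function(segments, gain_thr = 0.2, loss_thr = -0.2,
                          amp_thr = 1.5, homdel_thr = -1.5) {
  stopifnot(loss_thr < 0, gain_thr > 0, gain_thr < amp_thr,
            loss_thr > homdel_thr)
  m <- segments$mean_log2
  call <- rep("NEUTRAL", length(m))
  call[m > gain_thr] <- "GAIN"
  call[m > amp_thr] <- "AMP"
  call[m < loss_thr] <- "LOSS"
  call[m < homdel_thr] <- "HOMDEL"
  segments$call <- call
  segments
}

#' Expected log2 ratio of a copy-number state diluted by stroma
#'
#' The clone-mixture rendering equation: a fraction `cellularity` of cells
#' at integer copy number `cn` mixed with diploid stroma gives
#' `log2((c * cn + (1 - c) * 2) / 2)`. Zero mixtures are floored at
#' `floor_log2` to avoid infinities (the rendering floor used for
#' homozygous deletions).
#'
#' @param cn Integer copy number (>= 0).
#' @param cellularity Tumour-cell fraction in `[0, 1]`.
#' @param floor_log2 Lower guard for the returned ratio (default -4).
#' @return Expected log2 ratio.
#' @export
expected_log2 <- function(cn, cellularity, floor_log2 = -4) {
  stopifnot(all(cn >= 0), all(cellularity >= 0 & cellularity <= 1))
  mix <- cellularity * cn + (1 - cellularity) * 2
  pmax(log2(mix / 2), floor_log2)
}

#' Flag a profile as abnormal or normal
#'
#' A profile is abnormal iff it carries at least one qualifying non-neutral
#' segment: at least `min_probes` probes and spanning at least `min_span_mb`.
#' Low-cellularity biopsies dilute single-copy changes below the calling
#' thresholds and so read as normal — the bookkeeping the study's clinical
#' table records. Also reports the aberrant fraction: the proportion of
#' autosomal probes in non-neutral segments.
#'
#' @param called_segments Output of [call_segments()].
#' @param min_probes Minimum probes for a qualifying segment (default 10).
#' @param min_span_mb Minimum span in Mb (default 2).
#' @param case_id,quadrant,week Optional sample identity carried through.
#' @return One-row data.frame: `case_id`, `quadrant`, `week`, `abnormal`,
#'   `aberrant_fraction`.
#' @export
flag_abnormal <- function(called_segments, min_probes = 10, min_span_mb = 2,
                          case_id = NA_character_, quadrant = NA_integer_,
                          week = NA_integer_) {
  stopifnot(min_probes >= 1)
  s <- called_segments
  qual <- s$call != "NEUTRAL" & s$n_probes >= min_probes &
    (s$end_bp - s$start_bp) >= min_span_mb * 1e6
  auto <- s$chrom != "X"
  frac <- if (any(auto)) {
    sum(s$n_probes[auto & s$call != "NEUTRAL"]) / sum(s$n_probes[auto])
  } else NA_real_
  data.frame(case_id = case_id, quadrant = quadrant, week = week,
             abnormal = any(qual), aberrant_fraction = frac,
             stringsAsFactors = FALSE)
}
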