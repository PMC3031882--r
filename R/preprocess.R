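#' Construct a probe-level CGH profile
#'
#' One sample's array: ordered probe-level log2 ratios plus the sample's
#' place in the study design (case, cervix quadrant 1-4, treatment week
#' 0/2/5) and, when scored, its histopathological cellularity.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos_bp`,
#'   `log2_ratio`, sorted by chromosome then position.
#' @param case_id Case identifier.
#' @param quadrant Quadrant 1-4.
#' @param week Week 0, 2 or 5.
#' @param cellularity Tumour-cell fraction in `[0, 1]`, or `NA` when unknown.
#' @return Object of class `probe_profile`.
#' @export
probe_profile <- function(probes, case_id, quadrant, week,
                          cellularity = NA_real_) {
  stopifnot(
    is.data.frame(probes),
    all(c("probe_id", "chrom", "pos_bp", "log2_ratio") %in% names(probes)),
    quadrant %in% 1:4, week %in% c(0, 2, 5),
    is.na(cellularity) || (cellularity >= 0 && cellularity <= 1)
  )
  for (ch in unique(probes$chrom)) {
    p <- probes$pos_bp[probes$chrom == ch]
    if (any(diff(p) <= 0)) stop("probes must be sorted by position within ", ch)
  }
  structure(list(case_id = case_id, quadrant = as.integer(quadrant),
                 week = as.integer(week), cellularity = cellularity,
                 probes = probes),
            class = "probe_profile")
}

#' @export
print.probe_profile <- function(x, ...) {
  cat(sprintf("<probe_profile> %s q%d wk%d: %d probes (cellularity %s)\n",
              x$case_id, x$quadrant, x$week, nrow(x$probes),
              ifelse(is.na(x$cellularity), "unknown",
                     sprintf("%.2f", x$cellularity))))
  invisible(x)
}

sample_id_of <- function(profile) {
  sprintf("q%d_wk%d", profile$quadrant, profile$week)
}

#' Median-normalise a profile
#'
#' Subtracts the median log2 ratio so the modal (diploid) state sits at 0.
#'
#' @param profile A `probe_profile`.
#' @return The profile with normalised log2 ratios (median 0).
#' @export
median_normalize <- function(profile) {
  if (!nrow(profile$probes)) stop("cannot normalise an empty profile")
  lr <- profile$probes$log2_ratio
  if (any(!is.finite(lr))) stop("non-finite log2 ratios")
  profile$probes$log2_ratio <- lr - median(lr)
  profile
}

#' Segment a profile by circular binary segmentation
#'
#' Recursively splits each chromosome's probe sequence at the arc
#' maximising the pooled-variance t statistic between probes inside and
#' outside the arc, accepting a split when its permutation p-value falls
#' below `alpha`, until no further split is significant. Adjacent segments
#' whose means differ by less than `undo_sd` times the MAD of the probe
#' residuals are then re-merged (pruning of calls below the noise floor).
#' Chromosomes with fewer than 4 probes are returned as single segments.
#' Deterministic given `seed`: each chromosome gets its own permutation
#' stream derived from the global seed.
#'
#' @param profile A (normalised) `probe_profile`.
#' @param alpha Permutation significance level for accepting a split.
#' @param n_perm Number of permutations per split test (>= 100).
#' @param seed Integer seed for the permutation streams.
#' @param undo_sd Undo threshold in units of the residual MAD; `0` disables
#'   merging.
#' @param min_width Smallest number of probes for which a split test is run.
#' @return data.frame of segments: `chrom`, `start_bp`, `end_bp` (half-open,
#'   anchored on probe positions), `n_probes`, `mean_log2`. Segments are
#'   contiguous and cover every probe of each chromosome.
#' @export
cbs_segment <- function(profile, alpha = 0.01, n_perm = 10000, seed = 1,
                        undo_sd = 1, min_width = 4) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, min_width >= 4)
  probes <- profile$probes
  chroms <- unique(probes$chrom)
  out <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    p <- probes[probes$chrom == ch, , drop = FALSE]
    if (any(diff(p$pos_bp) <= 0)) stop("unsorted probes on chromosome ", ch)
    x <- p$log2_ratio
    n <- length(x)
    chrom_seed <- (abs(seed) %% 1000003L) * 1009L + ci * 97L
    bounds <- segment_sequence(x, alpha, n_perm, chrom_seed, min_width)
    if (undo_sd > 0 && nrow(bounds) > 1) {
      bounds <- undo_merge(x, bounds, undo_sd)
    }
    out[[ci]] <- data.frame(
      chrom = ch,
      start_bp = p$pos_bp[bounds$from],
      end_bp = p$pos_bp[bounds$to] + 1,
      n_probes = bounds$to - bounds$from + 1L,
      mean_log2 = vapply(seq_len(nrow(bounds)), function(k)
        mean(x[bounds$from[k]:bounds$to[k]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Recursive CBS on one chromosome's ratio vector; returns data.frame of
# probe-index ranges (from, to), 1-based inclusive, in genomic order.
segment_sequence <- function(x, alpha, n_perm, chrom_seed, min_width) {
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    (chrom_seed + counter * 131L) %% 2147483647L
  }
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < min_width) return(data.frame(from = lo, to = hi))
    res <- cbs_split_test(x[lo:hi], n_perm, alpha, next_seed())
    if (!isTRUE(res$significant)) return(data.frame(from = lo, to = hi))
    i <- res$i; j <- res$j  # arc (i, j], 0-based within lo:hi
    cuts <- unique(c(i, j))
    cuts <- cuts[cuts > 0 & cuts < n]
    if (!length(cuts)) return(data.frame(from = lo, to = hi))
    starts <- lo + c(0L, cuts)
    ends <- lo + c(cuts, n) - 1L
    do.call(rbind, lapply(seq_along(starts), function(k)
      recurse(starts[k], ends[k])))
  }
  b <- recurse(1L, length(x))
  b[order(b$from), , drop = FALSE]
}

# Merge adjacent segments whose means differ by < undo_sd * MAD of the
# probe-level residuals, closest pair first.
undo_merge <- function(x, bounds, undo_sd) {
  repeat {
    if (nrow(bounds) < 2) return(bounds)
    means <- vapply(seq_len(nrow(bounds)), function(k)
      mean(x[bounds$from[k]:bounds$to[k]]), numeric(1))
    resid <- x - rep(means, bounds$to - bounds$from + 1L)
    noise <- mad(resid)
    if (noise == 0) return(bounds)
    diffs <- abs(diff(means))
    k <- which.min(diffs)
    if (diffs[k] >= undo_sd * noise) return(bounds)
    bounds$to[k] <- bounds$to[k + 1]
    bounds <- bounds[-(k + 1), , drop = FALSE]
    rownames(bounds) <- NULL
  }
}
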