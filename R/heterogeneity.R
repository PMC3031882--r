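#' Subset an event matrix to a set of samples
#'
#' Drops catalogue columns no longer present in any retained sample is NOT
#' done: the catalogue is case-wide and column identity must be stable
#' across subsets.
#'
#' @param matrix An `event_matrix`.
#' @param ids Sample identifiers to keep.
#' @return An `event_matrix` over the selected samples.
#' @export
subset_event_matrix <- function(matrix, ids) {
  keep <- matrix$samples$sample_id %in% ids
  matrix$samples <- matrix$samples[keep, , drop = FALSE]
  matrix$presence <- matrix$presence[matrix$samples$sample_id, , drop = FALSE]
  matrix
}

aberrant_ids <- function(matrix, statuses = NULL) {
  ids <- matrix$samples$sample_id
  if (is.null(statuses)) return(ids)
  ab <- statuses$sample_id[statuses$abnormal]
  intersect(ids, ab)
}

#' Assign samples to genetic subpopulations
#'
#' Average-linkage hierarchical clustering of the aberrant samples under
#' the event Hamming distance, cut at the largest merge-height gap, subject
#' to a minimum between-cluster separation of `d_split` events (below it,
#' differences are treated as subclonal variation within one population).
#' Labels (`"A"`, `"B"`, ...) are ordered by share of week-0 samples, then
#' by overall size.
#'
#' @param matrix An `event_matrix` (aberrant samples).
#' @param statuses Optional profile-status data.frame (`sample_id`,
#'   `abnormal`); non-abnormal samples are excluded — their flat profiles
#'   reflect low cellularity, not genotype.
#' @param d_split Minimum event distance separating two subpopulations
#'   (default 3).
#' @return Named character vector: sample_id -> label.
#' @export
assign_subpopulations <- function(matrix, statuses = NULL, d_split = 3) {
  ids <- aberrant_ids(matrix, statuses)
  if (!length(ids)) stop("no aberrant samples: no tumour profile to cluster")
  if (length(ids) == 1) return(setNames("A", ids))
  m <- subset_event_matrix(matrix, ids)
  d <- event_distance_matrix(m)
  hc <- hclust(as.dist(d), method = "average")
  h <- sort(hc$height)
  k <- 1L
  if (max(h) >= d_split) {
    gaps <- diff(c(0, h))
    # a merge below d_split cannot separate clusters
    gaps[h < d_split] <- -Inf
    cut_at <- which.max(gaps)  # first merge of the "wide gap"
    k <- length(ids) - cut_at + 1L
  }
  cl <- cutree(hc, k = k)
  order_labels(cl, m)
}

order_labels <- function(cl, matrix) {
  ids <- names(cl)
  wk0 <- matrix$samples$week == 0
  names(wk0) <- matrix$samples$sample_id
  score <- vapply(unique(cl), function(g) {
    members <- ids[cl == g]
    sum(wk0[members]) * 1000 + length(members)
  }, numeric(1))
  ranked <- unique(cl)[order(-score, unique(cl))]
  setNames(LETTERS[match(cl, ranked)], ids)
}

#' Consensus genotype of each subpopulation
#'
#' An event belongs to a label's consensus when present in at least half of
#' that label's samples — tolerant of detection dropout in low-cellularity
#' biopsies.
#'
#' @param matrix An `event_matrix`.
#' @param labels Output of [assign_subpopulations()].
#' @return Logical matrix, labels x catalogue events.
#' @export
consensus_genotypes <- function(matrix, labels) {
  labs <- sort(unique(labels))
  out <- t(vapply(labs, function(l) {
    rows <- presence_rows(matrix, names(labels)[labels == l])
    colMeans(rows) >= 0.5
  }, logical(ncol(matrix$presence))))
  rownames(out) <- labs
  out
}

#' Classify catalogue events as homogeneous or heterogeneous
#'
#' A homogeneous (`HOM`) event is carried by every tumour subpopulation of
#' the case; anything else is heterogeneous (`HET`). In `"consensus"` mode
#' (default) the rule is applied over subpopulation consensus genotypes, so
#' one dropout sample does not veto `HOM`; in `"raw"` mode an event must be
#' present in every aberrant sample. Normal-profile samples never
#' participate: their flat profiles reflect stromal dilution, not genotype.
#'
#' @param matrix An `event_matrix`.
#' @param statuses Optional status table used to drop non-abnormal samples.
#' @param mode `"consensus"` or `"raw"`.
#' @param labels Subpopulation labels (computed if missing and needed).
#' @param d_split Passed to [assign_subpopulations()] when labels are
#'   computed here.
#' @return Object of class `het_call`: data.frame of the catalogue with
#'   `status` (`HOM`/`HET`) and `present_in` (comma-separated sample list).
#' @export
classify_hom_het <- function(matrix, statuses = NULL,
                             mode = c("consensus", "raw"), labels = NULL,
                             d_split = 3) {
  mode <- match.arg(mode)
  ids <- aberrant_ids(matrix, statuses)
  if (!length(ids)) stop("no aberrant samples: no tumour profile")
  m <- subset_event_matrix(matrix, ids)
  if (mode == "consensus") {
    if (is.null(labels)) {
      labels <- assign_subpopulations(matrix, statuses, d_split = d_split)
    }
    cons <- consensus_genotypes(m, labels[ids])
    hom <- colSums(cons) == nrow(cons)
  } else {
    hom <- colSums(m$presence) == nrow(m$presence)
  }
  out <- as.data.frame(m$events)
  out$status <- ifelse(hom, "HOM", "HET")
  out$present_in <- vapply(seq_len(ncol(m$presence)), function(j)
    paste(rownames(m$presence)[m$presence[, j]], collapse = ","),
    character(1))
  class(out) <- c("het_call", "data.frame")
  out
}

#' Case-level heterogeneity verdict
#'
#' Counts distinct subpopulations and flags the case as genetically
#' heterogeneous when two or more are present. The default
#' `"inferred"` mode counts every subpopulation ever observed (a clone
#' first seen after treatment started is inferred to have pre-existed below
#' the detection threshold — a clone could not plausibly arise and sweep
#' all quadrants within two weeks of therapy); `"week0"` mode counts only
#' labels among week-0 aberrant samples.
#'
#' @param labels Output of [assign_subpopulations()].
#' @param matrix The case `event_matrix`.
#' @param het A `het_call` for the case (for monoclonal support).
#' @param mode `"inferred"` (default) or `"week0"`.
#' @return Object of class `case_verdict`: list with `case_id`,
#'   `n_subpopulations`, `n_subpopulations_week0`, `heterogeneous`,
#'   `monoclonal_support` (the HOM events).
#' @export
case_verdict <- function(labels, matrix, het = NULL,
                         mode = c("inferred", "week0")) {
  mode <- match.arg(mode)
  ids <- names(labels)
  weeks <- matrix$samples$week[match(ids, matrix$samples$sample_id)]
  n_wk0 <- length(unique(labels[weeks == 0]))
  n_all <- length(unique(labels))
  n <- if (mode == "inferred") n_all else n_wk0
  support <- if (!is.null(het)) het[het$status == "HOM", , drop = FALSE]
  structure(list(case_id = matrix$case_id,
                 n_subpopulations = n,
                 n_subpopulations_week0 = n_wk0,
                 heterogeneous = n >= 2,
                 monoclonal_support = support),
            class = "case_verdict")
}

#' @export
print.case_verdict <- function(x, ...) {
  cat(sprintf("<case_verdict> %s: %d subpopulation(s) (%d at week 0) -> %s\n",
              x$case_id, x$n_subpopulations, x$n_subpopulations_week0,
              if (x$heterogeneous) "heterogeneous" else "homogeneous"))
  invisible(x)
}
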