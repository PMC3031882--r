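#' Build a per-case phylogeny over sample genotypes
#'
#' Neighbour-joining tree on the event Hamming distance between the
#' aberrant samples' presence rows, with an artificial diploid normal (an
#' all-zero genotype) included to give perspective on evolutionary
#' distance. Branch lengths are in event units; under a perfect phylogeny
#' with complete detection the distance matrix is additive and NJ recovers
#' the clone topology exactly. Negative NJ branch lengths are clamped to
#' zero with the deficit transferred to the sibling branch, preserving
#' root-to-leaf path lengths.
#'
#' @param matrix An `event_matrix` (aberrant samples only).
#' @param statuses Optional status table used to drop non-abnormal samples.
#' @param outgroup Name of the diploid outgroup leaf (default `"NORMAL"`).
#' @param prefix Optional prefix for leaf names (e.g. the case id, giving
#'   leaves like `CE01-13_q1_wk0`).
#' @return Object of class `case_tree`: list with `case_id`, `tree` (an
#'   unrooted `ape::phylo`), `rooted` (displayed rooted at the outgroup)
#'   and `dist` (the input distance matrix).
#' @export
build_tree <- function(matrix, statuses = NULL, outgroup = "NORMAL",
                       prefix = NULL) {
  ids <- aberrant_ids(matrix, statuses)
  if (length(ids) < 1) stop("need at least 2 leaves (including the outgroup)")
  m <- subset_event_matrix(matrix, ids)
  d <- event_distance_matrix(m, extra_rows = setNames(
    list(rep(FALSE, ncol(m$presence))), outgroup))
  if (!is.null(prefix)) {
    keep <- rownames(d) != outgroup
    rownames(d)[keep] <- paste(prefix, rownames(d)[keep], sep = "_")
    colnames(d) <- rownames(d)
  }
  n <- nrow(d)
  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = rep(d[1, 2] / 2, 2),
                 tip.label = rownames(d), Nnode = 1L)
    class(tree) <- "phylo"
  } else {
    tree <- ape::nj(as.dist(d))
    tree <- clamp_negative_edges(tree)
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  structure(list(case_id = matrix$case_id, tree = tree, rooted = rooted,
                 dist = d),
            class = "case_tree")
}

# Set negative branch lengths to 0, moving the deficit onto the sibling
# branch under the same parent node, so leaf-to-leaf paths through the
# parent are preserved where possible.
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) return(tree)
    e <- neg[which.min(tree$edge.length[neg])]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      s <- sibs[1]
      tree$edge.length[s] <- tree$edge.length[s] + deficit
      if (tree$edge.length[s] < 0) tree$edge.length[s] <- 0
    }
  }
}

#' @export
print.case_tree <- function(x, ...) {
  cat(sprintf("<case_tree> %s: %d leaves\n", x$case_id,
              length(x$tree$tip.label)))
  invisible(x)
}

#' Leaf-to-leaf path lengths of a case tree
#'
#' @param case_tree A `case_tree`.
#' @return Symmetric matrix of summed branch lengths between leaves.
#' @export
tree_path_lengths <- function(case_tree) {
  ape::cophenetic.phylo(case_tree$tree)
}

#' Infer early (trunk) events of a case
#'
#' Subpopulations only share events that occurred before their divergence,
#' so the earliest events are those common to all subpopulations: the
#' trunk is the intersection of the subpopulation consensus genotypes, and
#' every other catalogue event is a branch event. An empty intersection
#' would contradict a monoclonal origin and triggers a warning.
#'
#' @param matrix An `event_matrix`.
#' @param labels Subpopulation labels over the matrix samples.
#' @return Object of class `early_report`: the catalogue with `class`
#'   (`TRUNK`/`BRANCH`) and `lineages` (labels whose consensus carries the
#'   event). Trunk gains with a nested trunk further gain are reported
#'   with both intervals via the `nested_in` column.
#' @export
infer_early_events <- function(matrix, labels) {
  ids <- names(labels)
  m <- subset_event_matrix(matrix, ids)
  cons <- consensus_genotypes(m, labels)
  trunk <- colSums(cons) == nrow(cons)
  if (!any(trunk)) {
    warning("empty trunk: no event common to all subpopulations ",
            "(contradicts a monoclonal origin)")
  }
  out <- as.data.frame(m$events)
  out$class <- ifelse(trunk, "TRUNK", "BRANCH")
  out$lineages <- vapply(seq_len(ncol(cons)), function(j)
    paste(rownames(cons)[cons[, j]], collapse = ","), character(1))
  out$nested_in <- NA_character_
  tr <- which(trunk)
  for (i in tr) {
    if (out$kind[i] != "FURTHER_GAIN") next
    outer_gain <- tr[out$kind[tr] == "GAIN" & out$chrom[tr] == out$chrom[i] &
                       out$start_bp[tr] <= out$start_bp[i] &
                       out$end_bp[tr] >= out$end_bp[i]]
    if (length(outer_gain)) {
      out$nested_in[i] <- sprintf("%s %s", out$chrom[outer_gain[1]],
                                  format_event_position(
                                    new_event_table(out[outer_gain[1], 1:7])))
    }
  }
  class(out) <- c("early_report", "data.frame")
  out
}

#' Chromosome-level event ordering narrative
#'
#' Re-projects the early-event report onto one chromosome: which of its
#' events predate subpopulation divergence (trunk) and which arose
#' afterwards on particular lineages (branch).
#'
#' @param report An `early_report`.
#' @param chrom Chromosome name.
#' @return data.frame of the chromosome's events ordered by position, with
#'   `class` and `lineages`.
#' @export
order_chromosome_events <- function(report, chrom) {
  out <- report[report$chrom == as.character(chrom), , drop = FALSE]
  out <- out[order(out$start_bp, out$end_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
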