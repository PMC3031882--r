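#' Seeded end-to-end recovery suites
#'
#' Two canonical simulation benchmarks exercised by the tests and the
#' acceptance script, run end to end through segmentation, calling, event
#' matching, subpopulation assignment, trunk inference and trajectory
#' calling:
#'
#' * `"noiseless"`: pure tumour (cellularity 1), zero probe noise, events
#'   of at least 10 probes on a 2,000-probe grid; one sensitive
#'   (survival 0) and one resistant (survival 0.6) lineage sampled at
#'   weeks 0 and 5. Under these conditions the pipeline must recover the
#'   event catalogue, trunk set, subpopulation partition and trajectory
#'   classes exactly.
#' * `"noisy"`: probe noise sd 0.15 log2 units, cellularity uniform on
#'   0.4-0.9, single-copy gains/losses of at least 20 probes on the
#'   default 4,000-probe grid, sampled at week 0. Event matching and
#'   landmark snapping use a 3 Mb tolerance (about four probe spacings at
#'   this grid pitch). Scored on trunk-event recovery and exact partition
#'   match.
#'
#' @param kind `"noiseless"` or `"noisy"`.
#' @param n_runs Number of seeded replicates.
#' @param base_seed Base seed; run `r` uses `base_seed + r`.
#' @return data.frame with one row per run: the [score_recovery()] fields.
#' @export
recovery_suite <- function(kind = c("noiseless", "noisy"), n_runs = 50,
                           base_seed = 1000) {
  kind <- match.arg(kind)
  rows <- vector("list", n_runs)
  genome <- NULL
  for (r in seq_len(n_runs)) {
    seed_r <- (base_seed + r) %% 2147480000
    if (kind == "noiseless") {
      cfg <- sim_config(n_trunk = 4, n_lineages = 2, n_branch = 6,
                        survival = c(0, 0.6), cellularity_range = c(1, 1),
                        noise_sd = 0, weeks = c(0, 5), n_probes = 2000,
                        min_event_mb = 14, min_event_probes = 10,
                        buffer_probes = 6, seed = seed_r)
      pcfg <- pipeline_config(n_perm = 300, seed = seed_r)
      score_tol <- 1; snap_tol <- 1
    } else {
      cfg <- sim_config(n_trunk = 4, n_lineages = 2, n_branch = 6,
                        survival = c(0, 0.6),
                        cellularity_range = c(0.4, 0.9), noise_sd = 0.15,
                        weeks = 0, n_probes = 4000, min_event_mb = 16,
                        min_event_probes = 20, p_further = 0,
                        kind_weights = c(GAIN = 0.5, LOSS = 0.5,
                                         AMP = 0, HOMDEL = 0),
                        buffer_probes = 6, seed = seed_r)
      pcfg <- pipeline_config(n_perm = 300, seed = seed_r, tol_mb = 3,
                              snap_tol_mb = 3)
      score_tol <- 3; snap_tol <- 3
    }
    if (is.null(genome)) genome <- genome_model(n_probes = cfg$n_probes)
    sim <- simulate_study(cfg, genome = genome)
    res <- analyze_profiles(sim$profiles, sim$genome, pcfg)
    sc <- score_recovery(res, sim, score_tol_mb = score_tol,
                         snap_tol_mb = snap_tol)
    rows[[r]] <- data.frame(run = r, seed = seed_r,
                            catalogue_exact = sc$catalogue_exact,
                            trunk_complete = sc$trunk_complete,
                            trunk_exact = sc$trunk_exact,
                            partition_match = sc$partition_match,
                            trajectory_accuracy = sc$trajectory_accuracy,
                            abnormal_match = sc$abnormal_match)
  }
  do.call(rbind, rows)
}

#' Tree-additivity suite on perfect-phylogeny inputs
#'
#' Simulates clone phylogenies, builds the sample event matrix directly
#' from the leaf genotypes (complete detection), and checks that every
#' leaf-to-leaf path length in the NJ tree equals the event Hamming
#' distance. On additive matrices NJ is exact, so the maximum absolute
#' deviation should be numerical zero.
#'
#' @param n_runs Number of seeded replicates.
#' @param base_seed Base seed.
#' @return data.frame with one row per run: `max_deviation`,
#'   `topology_ok` (every simulated lineage forms its own clade).
#' @export
additivity_suite <- function(n_runs = 50, base_seed = 5000) {
  genome <- genome_model(n_probes = 600)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed_r <- (base_seed + r) %% 2147480000
    cfg <- sim_config(n_trunk = 3, n_lineages = 3, n_branch = 4,
                      n_probes = 600, min_event_mb = 20,
                      min_event_probes = 3, seed = seed_r)
    clones <- simulate_clone_phylogeny(cfg, genome)
    mat <- clone_event_matrix(clones)
    tree <- build_tree(mat)
    cop <- tree_path_lengths(tree)
    ids <- rownames(tree$dist)
    dev <- max(abs(cop[ids, ids] - tree$dist[ids, ids]))
    rows[[r]] <- data.frame(run = r, seed = seed_r, max_deviation = dev)
  }
  do.call(rbind, rows)
}

#' Event matrix of simulated leaf clones (complete detection)
#'
#' Each leaf clone contributes one sample (quadrant = lineage index,
#' week 0) carrying exactly its event set — the idealised matrix the
#' analysis would see with perfect detection.
#'
#' @param clone_set A `clone_set`.
#' @return An `event_matrix`.
#' @export
clone_event_matrix <- function(clone_set) {
  leaves <- setdiff(names(clone_set$clones), "ROOT")
  lists <- lapply(seq_along(leaves), function(i) {
    ev <- clone_set$clones[[leaves[i]]]$events
    new_event_table(as.data.frame(ev)[, c("chrom", "start_bp", "end_bp",
                                          "start_anchor", "end_anchor",
                                          "kind", "level")])
  })
  names(lists) <- sprintf("q%d_wk0", seq_along(leaves))
  match_events(lists, case_id = "CLONES", tol_mb = 0)
}
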