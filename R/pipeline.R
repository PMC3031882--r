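#' Pipeline configuration
#'
#' All tunable parameters of the analysis in one resolved list, logged by
#' [run_pipeline()] for reproducibility.
#'
#' @param alpha CBS split significance level.
#' @param n_perm CBS permutations per split test.
#' @param undo_sd CBS undo threshold (residual MADs).
#' @param gain_thr,loss_thr,amp_thr,homdel_thr Calling thresholds (log2).
#' @param min_probes,min_span_mb Abnormality qualification for a segment.
#' @param tol_mb Event-matching endpoint tolerance.
#' @param snap_tol_mb Landmark snap tolerance.
#' @param event_min_probes Probe floor for emitted events (suppresses
#'   single-probe noise spikes).
#' @param d_split Minimum event distance between subpopulations.
#' @param verdict_mode `"inferred"` or `"week0"` (see [case_verdict()]).
#' @param use_cellularity Use known cellularity when estimating copy levels.
#' @param seed Global seed (drives the CBS permutation streams).
#' @param verbose Emit one structured log line per stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.01, n_perm = 10000, undo_sd = 1,
                            gain_thr = 0.2, loss_thr = -0.2,
                            amp_thr = 1.5, homdel_thr = -1.5,
                            min_probes = 10, min_span_mb = 2,
                            tol_mb = 1, snap_tol_mb = 1,
                            event_min_probes = 5, d_split = 3,
                            verdict_mode = "inferred",
                            use_cellularity = TRUE, seed = 1,
                            verbose = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

log_stage <- function(config, stage, ...) {
  if (isTRUE(config$verbose)) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
}

#' Analyse the profiles of one case
#'
#' The full per-case chain: median normalisation, CBS segmentation,
#' copy-number calling, abnormality flagging, segment-to-event conversion,
#' cross-sample event matching, subpopulation assignment, hom/het
#' classification, case verdict, phylogeny, early-event inference,
#' subpopulation map and trajectory calls.
#'
#' @param profiles Named list of `probe_profile`s (one case).
#' @param genome The `genome_model` the probes live on.
#' @param config A `pipeline_config`.
#' @param case_id Case label (defaults to the first profile's).
#' @return List with `statuses`, `segments`, `called`, `events`, `matrix`,
#'   `labels`, `het`, `verdict`, `tree`, `early`, `map`, `trajectories`.
#'   When no profile is abnormal, the genotype-level entries are `NULL` and
#'   `verdict` reports zero subpopulations.
#' @export
analyze_profiles <- function(profiles, genome, config = pipeline_config(),
                             case_id = NULL) {
  stopifnot(length(profiles) >= 1)
  if (is.null(case_id)) case_id <- profiles[[1]]$case_id
  statuses <- NULL
  called_all <- list()
  seg_all <- list()
  event_lists <- list()
  for (k in seq_along(profiles)) {
    p <- median_normalize(profiles[[k]])
    sid <- sample_id_of(p)
    segs <- cbs_segment(p, alpha = config$alpha, n_perm = config$n_perm,
                        seed = config$seed + 977L * k,
                        undo_sd = config$undo_sd)
    called <- call_segments(segs, gain_thr = config$gain_thr,
                            loss_thr = config$loss_thr,
                            amp_thr = config$amp_thr,
                            homdel_thr = config$homdel_thr)
    st <- flag_abnormal(called, min_probes = config$min_probes,
                        min_span_mb = config$min_span_mb,
                        case_id = case_id, quadrant = p$quadrant,
                        week = p$week)
    st$sample_id <- sid
    statuses <- rbind(statuses, st)
    seg_all[[sid]] <- segs
    called_all[[sid]] <- called
    if (st$abnormal) {
      cell <- if (isTRUE(config$use_cellularity)) p$cellularity else NA_real_
      event_lists[[sid]] <- segments_to_events(
        called, genome, cellularity = cell,
        snap_tol_mb = config$snap_tol_mb,
        min_probes = config$event_min_probes)
    }
  }
  log_stage(config, "segment", "case %s: %d samples, %d abnormal",
            case_id, length(profiles), sum(statuses$abnormal))
  if (!length(event_lists)) {
    labels <- setNames(character(0), character(0))
    map <- build_map(statuses, labels, case_id)
    return(list(statuses = statuses, segments = seg_all,
                called = called_all, events = event_lists, matrix = NULL,
                labels = labels, het = NULL, verdict = NULL, tree = NULL,
                early = NULL, map = map,
                trajectories = call_trajectories(map)))
  }
  qw <- parse_sample_id(names(event_lists))
  mat <- match_events(event_lists,
                      samples = data.frame(quadrant = qw$quadrant,
                                           week = qw$week),
                      case_id = case_id, tol_mb = config$tol_mb)
  labels <- assign_subpopulations(mat, d_split = config$d_split)
  het <- classify_hom_het(mat, labels = labels, mode = "consensus")
  verdict <- case_verdict(labels, mat, het, mode = config$verdict_mode)
  tree <- build_tree(mat, prefix = NULL)
  early <- infer_early_events(mat, labels)
  map <- build_map(statuses, labels, case_id)
  traj <- call_trajectories(map)
  log_stage(config, "analyse",
            "case %s: %d events, %d subpopulation(s), trunk %d",
            case_id, nrow(mat$events), verdict$n_subpopulations,
            sum(early$class == "TRUNK"))
  list(statuses = statuses, segments = seg_all, called = called_all,
       events = event_lists, matrix = mat, labels = labels, het = het,
       verdict = verdict, tree = tree, early = early, map = map,
       trajectories = traj)
}

#' Fixture-mode analysis of a published case
#'
#' Runs the event-level stages (matching, subpopulation assignment,
#' hom/het classification, verdict, phylogeny, early events, map,
#' trajectories) directly from the packaged rearrangement and bookkeeping
#' tables, skipping segmentation — the canonical in-study input for
#' event-level analysis.
#'
#' @param case_id `"CE01-02"`, `"CE01-09"` or `"CE01-13"`.
#' @param config A `pipeline_config`.
#' @return List as [analyze_profiles()], plus `status_published` (the
#'   printed Hom/Het column aligned with the catalogue).
#' @export
analyze_case_fixture <- function(case_id, config = pipeline_config()) {
  fx <- fixture_case(case_id)
  mat <- fx$matrix
  labels <- assign_subpopulations(mat, d_split = config$d_split)
  het <- classify_hom_het(mat, labels = labels, mode = "consensus")
  verdict <- case_verdict(labels, mat, het, mode = config$verdict_mode)
  tree <- build_tree(mat, prefix = case_id)
  early <- infer_early_events(mat, labels)
  map <- build_map(fx$statuses, labels, case_id)
  traj <- call_trajectories(map)
  list(statuses = fx$statuses, matrix = mat, labels = labels, het = het,
       verdict = verdict, tree = tree, early = early, map = map,
       trajectories = traj, status_published = fx$status_published)
}

#' Run the full pipeline over a directory of probe tables
#'
#' Reads every `<case>_q<quadrant>_wk<week>.tsv` under `input_dir`, groups
#' by case, runs [analyze_profiles()] per case, and writes the standard
#' artefacts (SEG, called-segment BED, het report CSV, Newick tree, map
#' CSV, trajectory JSON) under `out_dir`.
#'
#' @param input_dir Directory of probe tables.
#' @param out_dir Output directory (created if needed).
#' @param genome The `genome_model`.
#' @param config A `pipeline_config`.
#' @return Named list of per-case results, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, genome,
                         config = pipeline_config()) {
  files <- list.files(input_dir, pattern = "_q[0-9]_wk[0-9]\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("no probe tables found under ", input_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  profiles <- lapply(files, read_probe_table)
  cases <- split(profiles, vapply(profiles, `[[`, "", "case_id"))
  results <- list()
  for (case_id in names(cases)) {
    ps <- cases[[case_id]]
    names(ps) <- vapply(ps, sample_id_of, "")
    res <- analyze_profiles(ps, genome, config, case_id = case_id)
    for (sid in names(res$segments)) {
      write_seg(res$segments[[sid]],
                file.path(out_dir, sprintf("%s_%s.seg", case_id, sid)),
                id = sprintf("%s_%s", case_id, sid))
      write_bed(res$called[[sid]],
                file.path(out_dir, sprintf("%s_%s.bed", case_id, sid)))
    }
    if (!is.null(res$het)) {
      write_het_report(res$het,
                       file.path(out_dir, paste0(case_id, "_events.csv")),
                       case_id = case_id)
      write_newick(res$tree, file.path(out_dir, paste0(case_id, ".nwk")))
    }
    write_map_csv(res$map, file.path(out_dir, paste0(case_id, "_map.csv")))
    write_trajectory_json(res$trajectories,
                          file.path(out_dir,
                                    paste0(case_id, "_trajectories.json")))
    results[[case_id]] <- res
  }
  invisible(results)
}

#' Score a pipeline result against simulation ground truth
#'
#' @param result Output of [analyze_profiles()] on simulated profiles.
#' @param sim Output of [simulate_study()].
#' @param score_tol_mb Endpoint tolerance when matching recovered events to
#'   truth (default 2.5 Mb, about three probes on the 4,000-probe grid).
#' @param snap_tol_mb Landmark snap tolerance used to re-anchor the truth
#'   events before comparison; must equal the analysis snap tolerance so
#'   both sides use one anchoring policy.
#' @return List of logical/numeric scores: `catalogue_exact`,
#'   `trunk_complete`, `trunk_exact`, `partition_match`,
#'   `trajectory_accuracy`, `abnormal_match`.
#' @export
score_recovery <- function(result, sim, score_tol_mb = 2.5,
                           snap_tol_mb = 1) {
  truth_cat <- snap_event_anchors(truth_event_catalogue(sim$clones),
                                  sim$genome, snap_tol_mb = snap_tol_mb)
  truth_trunk <- snap_event_anchors(sim$clones$clones$ROOT$events,
                                    sim$genome, snap_tol_mb = snap_tol_mb)
  rec_cat <- if (!is.null(result$matrix)) result$matrix$events else
    empty_event_table()
  catalogue_exact <- setequal(event_key(truth_cat), event_key(rec_cat))
  rec_trunk <- if (!is.null(result$early)) {
    new_event_table(as.data.frame(result$early)[
      result$early$class == "TRUNK", 1:7, drop = FALSE])
  } else empty_event_table()
  trunk_complete <- all(vapply(seq_len(nrow(truth_trunk)), function(i)
    events_match_any(truth_trunk[i, ], rec_trunk, score_tol_mb), logical(1)))
  trunk_exact <- setequal(event_key(truth_trunk), event_key(rec_trunk))
  # true partition over truly-detectable-aberrant samples
  tm <- truth_map(sim$truth)
  true_groups <- list()
  called_groups <- list()
  for (r in seq_len(nrow(sim$truth$grid))) {
    g <- sim$truth$grid[r, ]
    if (!g$present) next
    sid <- sprintf("q%d_wk%d", g$quadrant, g$week)
    lab <- tm[g$quadrant, paste0("wk", g$week)]
    if (is_label(lab)) true_groups[[lab]] <- c(true_groups[[lab]], sid)
  }
  for (sid in names(result$labels)) {
    lab <- result$labels[[sid]]
    called_groups[[lab]] <- c(called_groups[[lab]], sid)
  }
  partition_match <- setequal(
    lapply(true_groups, sort)[order(vapply(true_groups, min, ""))],
    lapply(called_groups, sort)[order(vapply(called_groups, min, ""))])
  sel <- selection_summary(sim$truth, result$trajectories)
  true_ab <- unlist(lapply(true_groups, identity), use.names = FALSE)
  called_ab <- result$statuses$sample_id[result$statuses$abnormal]
  list(catalogue_exact = catalogue_exact,
       trunk_complete = trunk_complete,
       trunk_exact = trunk_exact,
       partition_match = partition_match,
       trajectory_accuracy = sel$accuracy,
       abnormal_match = setequal(true_ab, called_ab))
}

# Scoring comparator: same chromosome, kind and level, endpoints within
# tolerance on resolved bp. Anchor tokens are a reporting dialect, not part
# of the genomic identity, so they are ignored here (unlike catalogue
# matching inside a case).
events_match_any <- function(ev, catalogue, tol_mb) {
  if (!nrow(catalogue)) return(FALSE)
  tol <- tol_mb * 1e6 + 1
  any(catalogue$chrom == ev$chrom & catalogue$kind == ev$kind &
        catalogue$level == ev$level &
        abs(catalogue$start_bp - ev$start_bp) <= tol &
        abs(catalogue$end_bp - ev$end_bp) <= tol)
}
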