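#' Simulation configuration for synthetic clone-mixture studies
#'
#' Defines the study conditions the generator emulates: a monoclonal tumour
#' whose founder cell acquired `n_trunk` copy-number events, diverging into
#' `n_lineages` subpopulations with `n_branch` private events each (perfect
#' phylogeny: no event loss, no homoplasy). Each cervix quadrant is occupied
#' by one lineage; chemoradiotherapy multiplies each lineage's fraction by a
#' per-clone survival, tumour content (cellularity) shrinks accordingly, and
#' clones falling below the detectability floor are recorded as
#' undetectable.
#'
#' @param n_trunk Number of trunk (founder) events.
#' @param n_lineages Number of diverging lineages (>= 1).
#' @param n_branch Private events per lineage.
#' @param survival Per-lineage survival fraction over the full 5-week
#'   course (recycled to `n_lineages`). Default one sensitive and one
#'   resistant lineage.
#' @param cellularity_range Uniform range for per-biopsy tumour-cell
#'   fraction.
#' @param noise_sd Gaussian probe noise, log2 units.
#' @param detect_floor Smallest clone fraction of total cells that array
#'   CGH is assumed to detect (default 0.10).
#' @param minor_fraction Fraction of the tumour compartment held by a
#'   second, minor lineage in each quadrant (0 = spatially pure quadrants).
#' @param weeks Timepoints sampled (subset of 0, 2, 5).
#' @param n_probes Probe-grid size for [genome_model()].
#' @param min_event_mb,min_event_probes Smallest event size.
#' @param p_whole Probability an event is whole-chromosome.
#' @param p_further Probability a gain carries a nested further gain.
#' @param kind_weights Sampling weights for `GAIN`, `LOSS`, `AMP`, `HOMDEL`.
#' @param trunk_preset Optional `event_table` of fixed trunk events placed
#'   before random ones (see [cervical_preset()]).
#' @param buffer_probes Neutral probes required between events on one
#'   chromosome, and between a partial event and a chromosome end.
#' @param max_chrom_fraction Largest fraction of one chromosome's probes
#'   that partial-chromosome events may cover (whole-chromosome events are
#'   exempt); keeps a neutral majority per chromosome so separate events
#'   stay identifiable.
#' @param seed Integer seed; fully determines the simulated study.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_trunk = 4, n_lineages = 2, n_branch = 6,
                       survival = c(0.01, 0.5),
                       cellularity_range = c(0.4, 0.9),
                       noise_sd = 0.15, detect_floor = 0.10,
                       minor_fraction = 0, weeks = c(0, 5),
                       n_probes = 4000, min_event_mb = 2,
                       min_event_probes = 10, p_whole = 0.05,
                       p_further = 0.1,
                       kind_weights = c(GAIN = 0.45, LOSS = 0.45,
                                        AMP = 0.05, HOMDEL = 0.05),
                       trunk_preset = NULL, buffer_probes = 2,
                       max_chrom_fraction = 0.5, seed = 1) {
  stopifnot(n_lineages >= 1, n_trunk >= 0, n_branch >= 0,
            all(survival >= 0 & survival <= 1),
            detect_floor >= 0 && detect_floor <= 1,
            minor_fraction >= 0 && minor_fraction < 1,
            all(weeks %in% c(0, 2, 5)), noise_sd >= 0)
  structure(list(
    n_trunk = n_trunk, n_lineages = n_lineages, n_branch = n_branch,
    survival = rep_len(survival, n_lineages),
    cellularity_range = cellularity_range, noise_sd = noise_sd,
    detect_floor = detect_floor, minor_fraction = minor_fraction,
    weeks = sort(unique(weeks)), n_probes = n_probes,
    min_event_mb = min_event_mb, min_event_probes = min_event_probes,
    p_whole = p_whole, p_further = p_further, kind_weights = kind_weights,
    trunk_preset = trunk_preset, buffer_probes = buffer_probes,
    max_chrom_fraction = max_chrom_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Cervical-cancer trunk preset
#'
#' Fixed trunk events recurrently observed early in cervical
#' carcinogenesis: terminal 3q gain (the hallmark of the transition from
#' pre-malignant lesion to invasive carcinoma) and distal 11q loss.
#'
#' @param genome A `genome_model`.
#' @return An `event_table` to use as `trunk_preset` in [sim_config()].
#' @export
cervical_preset <- function(genome) {
  make_events(genome,
              chrom = c("3", "11"),
              start = list(153.8, 94.8),
              end = list("QTEL", "QTEL"),
              kind = c("GAIN", "LOSS"))
}

kind_delta <- function(kind) {
  unname(c(GAIN = 1L, LOSS = -1L, FURTHER_GAIN = 1L,
           AMP = 6L, HOMDEL = -2L)[kind])
}

local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a clone phylogeny of copy-number events
#'
#' Draws a rooted clone tree: the root (founder) clone carries exactly the
#' trunk events; each of `n_lineages` leaf clones adds its own private
#' branch events on intervals not overlapping any other event, so the
#' simulated genotypes form a perfect phylogeny by construction. Event
#' endpoints snap to probe positions; placement is uniform over chromosome
#' arms with log-uniform lengths between `min_event_mb` and the arm length,
#' plus a small probability of whole-chromosome events.
#'
#' @param config A `sim_config`.
#' @param genome A `genome_model`.
#' @return Object of class `clone_set`: list of clones (`ROOT` plus
#'   `L1..Lk`), each with `clone_id`, `parent` and an `event_table` with a
#'   `delta` copy-change column.
#' @export
simulate_clone_phylogeny <- function(config, genome) {
  local_seed(config$seed, {
    placer <- event_placer(genome, config)
    trunk <- empty_event_table()
    trunk$delta <- integer(0)
    if (!is.null(config$trunk_preset) && nrow(config$trunk_preset)) {
      preset <- snap_to_probes(config$trunk_preset, genome)
      preset$delta <- kind_delta(preset$kind)
      for (i in seq_len(nrow(preset))) placer$reserve(preset[i, ])
      trunk <- preset
    }
    n_random_trunk <- config$n_trunk - nrow(trunk)
    if (n_random_trunk > 0) {
      trunk <- rbind(trunk, placer$place(n_random_trunk))
    }
    clones <- list(ROOT = list(clone_id = "ROOT", parent = NA_character_,
                               events = sort_events(trunk)))
    for (l in seq_len(config$n_lineages)) {
      branch <- placer$place(config$n_branch)
      id <- paste0("L", l)
      clones[[id]] <- list(clone_id = id, parent = "ROOT",
                           events = sort_events(rbind(trunk, branch)))
    }
    structure(list(clones = clones), class = "clone_set")
  })
}

sort_events <- function(ev) {
  delta <- ev$delta
  ord <- order(match(ev$chrom, c(as.character(1:22), "X")),
               ev$start_bp, ev$end_bp, ev$kind)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("<clone_set> %d clones: %s\n", length(x$clones),
              paste(names(x$clones), collapse = ", ")))
  invisible(x)
}

# Closure managing non-overlapping event placement on the probe grid.
event_placer <- function(genome, config) {
  chrs <- genome$chromosomes
  used <- lapply(seq_len(nrow(chrs)), function(i) integer(0))  # probe indices
  names(used) <- chrs$chrom
  arm_list <- do.call(rbind, lapply(seq_len(nrow(chrs)), function(i) {
    data.frame(chrom = chrs$chrom[i],
               start_bp = c(0, chrs$centromere_bp[i]),
               end_bp = c(chrs$centromere_bp[i], chrs$length_bp[i]),
               stringsAsFactors = FALSE)
  }))
  probe_idx <- function(ch) which(genome$probes$chrom == ch)

  reserve <- function(ev) {
    pi <- probe_idx(ev$chrom)
    pos <- genome$probes$pos_bp[pi]
    inside <- pi[pos >= ev$start_bp & pos < ev$end_bp]
    if (!length(inside)) stop("preset event covers no probes")
    used[[ev$chrom]] <<- c(used[[ev$chrom]], inside)
  }

  blocked <- function(ch, idx) {
    u <- used[[ch]]
    if (!length(u)) return(FALSE)
    buf <- config$buffer_probes
    any(idx %in% unique(as.vector(outer(u, -buf:buf, `+`))))
  }

  place_one <- function(kind) {
    for (try in 1:500) {
      if (runif(1) < config$p_whole) {
        ch <- sample(chrs$chrom, 1)
        idx <- probe_idx(ch)
        if (length(idx) < config$min_event_probes || blocked(ch, idx)) next
        pos <- genome$probes$pos_bp[idx]
        ev <- data.frame(chrom = ch, start_bp = pos[1],
                         end_bp = pos[length(pos)] + 1,
                         start_anchor = "PTEL", end_anchor = "QTEL",
                         kind = kind, level = 1L, delta = kind_delta(kind),
                         stringsAsFactors = FALSE)
        used[[ch]] <<- c(used[[ch]], idx)
        return(ev)
      }
      a <- arm_list[sample(nrow(arm_list), 1), ]
      arm_mb <- (a$end_bp - a$start_bp) / 1e6
      if (arm_mb <= config$min_event_mb) next
      len_mb <- exp(runif(1, log(config$min_event_mb), log(arm_mb)))
      start <- runif(1, a$start_bp, a$end_bp - len_mb * 1e6)
      idx_all <- probe_idx(a$chrom)
      pos <- genome$probes$pos_bp[idx_all]
      inside <- idx_all[pos >= start & pos < start + len_mb * 1e6]
      if (length(inside) < config$min_event_probes) next
      if (blocked(a$chrom, inside)) next
      idx_chrom <- probe_idx(a$chrom)
      # an event must either reach the chromosome end or leave at least
      # buffer_probes neutral probes before it: shorter terminal gaps are
      # below the resolution of a permutation-tested split
      gap_left <- match(inside[1], idx_chrom) - 1L
      gap_right <- length(idx_chrom) - match(inside[length(inside)], idx_chrom)
      if ((gap_left > 0 && gap_left < config$buffer_probes) ||
          (gap_right > 0 && gap_right < config$buffer_probes)) next
      # cap per-chromosome aberrant fraction: identifiability of separate
      # events needs a neutral majority on the chromosome
      frac <- (length(used[[a$chrom]]) + length(inside)) / length(idx_chrom)
      if (frac > config$max_chrom_fraction) next
      pos_in <- genome$probes$pos_bp[inside]
      ev <- data.frame(chrom = a$chrom, start_bp = pos_in[1],
                       end_bp = pos_in[length(pos_in)] + 1,
                       start_anchor = "MB", end_anchor = "MB",
                       kind = kind, level = 1L, delta = kind_delta(kind),
                       stringsAsFactors = FALSE)
      ev <- snap_event_anchors(new_event_table(ev), genome)
      used[[a$chrom]] <<- c(used[[a$chrom]], inside)
      return(ev)
    }
    stop("genome too small to place the requested non-overlapping events")
  }

  place <- function(n) {
    if (n == 0) {
      out <- empty_event_table()
      out$delta <- integer(0)
      return(out)
    }
    kinds <- sample(names(config$kind_weights), n, replace = TRUE,
                    prob = config$kind_weights)
    rows <- list()
    for (k in kinds) {
      ev <- place_one(k)
      rows[[length(rows) + 1L]] <- ev
      if (k == "GAIN" && runif(1) < config$p_further) {
        inner <- nested_further_gain(ev, genome, config)
        if (!is.null(inner)) rows[[length(rows) + 1L]] <- inner
      }
    }
    sort_events(do.call(rbind, rows))
  }

  list(place = place, reserve = reserve)
}

nested_further_gain <- function(ev, genome, config) {
  idx <- which(genome$probes$chrom == ev$chrom &
                 genome$probes$pos_bp >= ev$start_bp &
                 genome$probes$pos_bp < ev$end_bp)
  m <- config$min_event_probes
  if (length(idx) < 3 * m) return(NULL)
  # strictly interior: leave >= 1 outer probe each side
  first <- sample((2):(length(idx) - m), 1)
  last <- min(first + m - 1 + sample(0:m, 1), length(idx) - 1)
  inner <- idx[first:last]
  pos <- genome$probes$pos_bp[inner]
  data.frame(chrom = ev$chrom, start_bp = pos[1],
             end_bp = pos[length(pos)] + 1,
             start_anchor = "MB", end_anchor = "MB",
             kind = "FURTHER_GAIN", level = 2L, delta = 1L,
             stringsAsFactors = FALSE)
}

snap_to_probes <- function(events, genome) {
  for (i in seq_len(nrow(events))) {
    idx <- which(genome$probes$chrom == events$chrom[i] &
                   genome$probes$pos_bp >= events$start_bp[i] &
                   genome$probes$pos_bp < events$end_bp[i])
    if (!length(idx)) stop("event covers no probes: ", event_key(events[i, ]))
    pos <- genome$probes$pos_bp[idx]
    events$start_bp[i] <- pos[1]
    events$end_bp[i] <- pos[length(pos)] + 1
  }
  snap_event_anchors(events, genome)
}

#' Per-probe integer copy number of a clone
#'
#' Diploid baseline plus the summed copy-change of every event overlapping
#' each probe, clamped at zero.
#'
#' @param clone_set A `clone_set`.
#' @param clone_id Clone identifier (`"ROOT"`, `"L1"`, ...).
#' @param genome The `genome_model` the clones were simulated on.
#' @return Integer vector, one entry per probe of `genome`.
#' @export
clone_copy_number <- function(clone_set, clone_id, genome) {
  ev <- clone_set$clones[[clone_id]]$events
  cn <- rep(2L, nrow(genome$probes))
  if (is.null(ev) || !nrow(ev)) return(cn)
  for (i in seq_len(nrow(ev))) {
    hit <- genome$probes$chrom == ev$chrom[i] &
      genome$probes$pos_bp >= ev$start_bp[i] &
      genome$probes$pos_bp < ev$end_bp[i]
    cn[hit] <- cn[hit] + ev$delta[i]
  }
  pmax(cn, 0L)
}

#' Build the week-0 spatial truth for a simulated study
#'
#' Each quadrant's tumour compartment is occupied by one dominant lineage
#' (lineages assigned round-robin over quadrants), optionally mixed with a
#' `minor_fraction` of the next lineage; per-biopsy cellularity is drawn
#' uniformly from `cellularity_range`.
#'
#' @param clone_set A `clone_set`.
#' @param config The `sim_config`.
#' @return Object of class `spatial_truth`: list with `grid` (quadrant,
#'   week, present, cellularity), `fractions` (rows = grid rows, columns =
#'   leaf clones; fractions of the tumour compartment) and `detectable`.
#' @export
simulate_truth_week0 <- function(clone_set, config) {
  leaves <- setdiff(names(clone_set$clones), "ROOT")
  grid <- data.frame(quadrant = 1:4, week = 0L, present = TRUE,
                     cellularity = NA_real_, stringsAsFactors = FALSE)
  local_seed(config$seed + 7L, {
    grid$cellularity <- runif(4, config$cellularity_range[1],
                              config$cellularity_range[2])
  })
  fr <- matrix(0, nrow = 4, ncol = length(leaves),
               dimnames = list(NULL, leaves))
  for (q in 1:4) {
    dom <- ((q - 1) %% length(leaves)) + 1
    fr[q, dom] <- 1 - config$minor_fraction
    if (config$minor_fraction > 0 && length(leaves) > 1) {
      minor <- (dom %% length(leaves)) + 1
      fr[q, minor] <- config$minor_fraction
    }
  }
  truth <- structure(list(grid = grid, fractions = fr,
                          detectable = NULL), class = "spatial_truth")
  truth$detectable <- detectability(truth, config$detect_floor)
  truth
}

detectability <- function(truth, floor) {
  det <- truth$fractions * truth$grid$cellularity >= floor
  det[!truth$grid$present, ] <- FALSE
  det
}

#' Evolve clone fractions under treatment selection
#'
#' Each clone's fraction is multiplied by its survival; the surviving
#' fractions are renormalised over the shrunken tumour compartment, and
#' cellularity is rescaled against the (unchanged) stromal compartment:
#' with tumour survival `S = sum(f * s)`, the new cellularity is
#' `c S / (c S + (1 - c))`. Clones whose fraction of total cells falls
#' below `detect_floor` are recorded as undetectable.
#'
#' @param truth A `spatial_truth` (typically the week-0 truth).
#' @param survival Named or positional vector of per-clone survival
#'   fractions in `[0, 1]`.
#' @param week Week label to stamp on the evolved rows.
#' @param detect_floor Detectability floor (fraction of total cells).
#' @return A new `spatial_truth` holding the evolved timepoint.
#' @export
evolve_fractions <- function(truth, survival, week = 5L,
                             detect_floor = 0.10) {
  stopifnot(all(survival >= 0 & survival <= 1))
  leaves <- colnames(truth$fractions)
  s <- if (!is.null(names(survival))) survival[leaves]
       else rep_len(survival, length(leaves))
  out <- truth
  out$grid$week <- as.integer(week)
  for (r in seq_len(nrow(out$grid))) {
    f <- truth$fractions[r, ] * s
    S <- sum(f)
    c0 <- truth$grid$cellularity[r]
    if (S <= 0 || is.na(c0)) {
      out$fractions[r, ] <- 0
      out$grid$cellularity[r] <- 0
    } else {
      out$fractions[r, ] <- f / S
      out$grid$cellularity[r] <- c0 * S / (c0 * S + (1 - c0))
    }
  }
  out$detectable <- detectability(out, detect_floor)
  out
}

#' Render probe-level profiles from a spatial truth
#'
#' For each sampled (quadrant, week) cell, the probe log2 ratio is
#' `log2((c * sum_i f_i cn_i(probe) + (1 - c) * 2) / 2) + N(0, noise_sd^2)`
#' with `c` the cellularity and `f` the clone fractions over tumour
#' content; zero mixtures are floored at `homdel_floor`. Deterministic
#' given `seed`.
#'
#' @param truth A `spatial_truth` (one or more timepoints; see
#'   [simulate_study()] for the combined object).
#' @param clone_set The simulated clones.
#' @param genome The `genome_model`.
#' @param noise_sd Gaussian probe noise (log2 units).
#' @param seed Integer seed.
#' @param case_id Case label stamped on the profiles.
#' @param homdel_floor Rendering floor for the log2 ratio (default -4).
#' @return Named list of `probe_profile` objects (`q<q>_wk<w>`); cells
#'   marked not present are excluded.
#' @export
render_probe_data <- function(truth, clone_set, genome, noise_sd = 0.15,
                              seed = 1, case_id = "SIM", homdel_floor = -4) {
  stopifnot(noise_sd >= 0)
  leaves <- colnames(truth$fractions)
  cn <- vapply(leaves, function(id) clone_copy_number(clone_set, id, genome),
               numeric(nrow(genome$probes)))
  profiles <- list()
  local_seed(seed, {
    for (r in seq_len(nrow(truth$grid))) {
      if (!truth$grid$present[r]) next
      c0 <- truth$grid$cellularity[r]
      f <- truth$fractions[r, ]
      tumour_cn <- if (sum(f) > 0) as.vector(cn %*% f) + (1 - sum(f)) * 2
                   else rep(2, nrow(genome$probes))
      mix <- c0 * tumour_cn + (1 - c0) * 2
      lr <- pmax(log2(mix / 2), homdel_floor)
      if (noise_sd > 0) lr <- lr + rnorm(length(lr), 0, noise_sd)
      probes <- data.frame(probe_id = genome$probes$probe_id,
                           chrom = genome$probes$chrom,
                           pos_bp = genome$probes$pos_bp,
                           log2_ratio = lr, stringsAsFactors = FALSE)
      prof <- probe_profile(probes, case_id, truth$grid$quadrant[r],
                            truth$grid$week[r], cellularity = c0)
      profiles[[sample_id_of(prof)]] <- prof
    }
  })
  profiles
}

#' Simulate a complete multi-quadrant, multi-timepoint study
#'
#' Ties the generator together: clone phylogeny, week-0 spatial truth,
#' treatment-selection evolution to the later timepoints (per-clone
#' survival applied with exposure proportional to elapsed weeks), and probe
#' rendering for every sampled cell.
#'
#' @param config A `sim_config`.
#' @param genome Optional `genome_model` (defaults to one built from
#'   `config$n_probes`).
#' @param case_id Case label.
#' @return List with `clones`, `genome`, `truth` (a `spatial_truth`
#'   covering all sampled weeks), and `profiles`.
#' @export
simulate_study <- function(config, genome = NULL, case_id = "SIM") {
  if (is.null(genome)) genome <- genome_model(n_probes = config$n_probes)
  clones <- simulate_clone_phylogeny(config, genome)
  wk0 <- simulate_truth_week0(clones, config)
  truths <- list()
  for (w in config$weeks) {
    truths[[as.character(w)]] <- if (w == 0) wk0 else
      evolve_fractions(wk0, config$survival^(w / 5), week = w,
                       detect_floor = config$detect_floor)
  }
  truth <- truths[[1]]
  if (length(truths) > 1) {
    truth$grid <- do.call(rbind, lapply(truths, `[[`, "grid"))
    truth$fractions <- do.call(rbind, lapply(truths, `[[`, "fractions"))
    truth$detectable <- do.call(rbind, lapply(truths, `[[`, "detectable"))
    rownames(truth$grid) <- NULL
  }
  profiles <- render_probe_data(truth, clones, genome,
                                noise_sd = config$noise_sd,
                                seed = config$seed + 13L, case_id = case_id)
  list(clones = clones, genome = genome, truth = truth, profiles = profiles)
}

#' Union catalogue of simulated events (ground truth)
#'
#' @param clone_set A `clone_set`.
#' @return An `event_table` containing each distinct event once.
#' @export
truth_event_catalogue <- function(clone_set) {
  all_ev <- do.call(rbind, lapply(clone_set$clones, function(cl)
    as.data.frame(cl$events)[, c("chrom", "start_bp", "end_bp",
                                 "start_anchor", "end_anchor",
                                 "kind", "level")]))
  if (is.null(all_ev) || !nrow(all_ev)) return(empty_event_table())
  ev <- new_event_table(all_ev)
  ev[!duplicated(event_key(ev)), , drop = FALSE]
}

#' Write a simulated study to disk as a reusable fixture
#'
#' One tab-delimited probe table per sample
#' (`<case>_q<quadrant>_wk<week>.tsv`, columns `probe_id`, `chrom`,
#' `pos_bp`, `log2_ratio`) plus a JSON truth manifest sufficient to score
#' recovery (clone events, sampling grid, clone fractions, detectability).
#'
#' @param profiles Named list of `probe_profile`s.
#' @param truth A `spatial_truth`.
#' @param clone_set The simulated clones.
#' @param dir Output directory (created if needed).
#' @param case_id Case label used in file names.
#' @return Invisibly, the manifest path.
#' @export
write_fixture <- function(profiles, truth, clone_set, dir, case_id = "SIM") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in profiles) {
    path <- file.path(dir, sprintf("%s_q%d_wk%d.tsv", case_id,
                                   p$quadrant, p$week))
    df <- p$probes
    df$log2_ratio <- sprintf("%.6f", df$log2_ratio)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    case_id = case_id,
    clones = lapply(clone_set$clones, function(cl) list(
      clone_id = cl$clone_id, parent = cl$parent,
      events = as.data.frame(cl$events)
    )),
    grid = truth$grid,
    fractions = as.data.frame(truth$fractions),
    detectable = as.data.frame(truth$detectable)
  )
  path <- file.path(dir, "truth.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Read a probe table written by [write_fixture()]
#'
#' @param path Path to a `<case>_q<quadrant>_wk<week>.tsv` file.
#' @param cellularity Optional cellularity to attach.
#' @return A `probe_profile`.
#' @export
read_probe_table <- function(path, cellularity = NA_real_) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos_bp", "log2_ratio")
  if (!all(need %in% names(df))) {
    stop("malformed probe table ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$log2_ratio))
  if (length(bad)) {
    stop("malformed probe table ", path, ": non-numeric log2_ratio at line(s) ",
         paste(head(bad + 1, 5), collapse = ", "))
  }
  m <- regmatches(basename(path),
                  regexec("^(.+)_q([0-9])_wk([0-9])\\.tsv$", basename(path)))[[1]]
  if (length(m) != 4) stop("cannot parse sample name from ", basename(path))
  df$chrom <- as.character(df$chrom)
  probe_profile(df, case_id = m[2], quadrant = as.integer(m[3]),
                week = as.integer(m[4]), cellularity = cellularity)
}
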