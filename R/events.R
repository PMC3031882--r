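#' @name events
#' @title Aberration events in the telomere/centromere dialect
#'
#' @description
#' An aberration event is a typed genomic interval: a copy-number change of a
#' given kind (`LOSS`, `GAIN`, `FURTHER_GAIN`, `AMP`, `HOMDEL`) whose
#' endpoints are either Mb coordinates or arm landmarks (`PTEL`, `CEN`,
#' `QTEL`). Events are held as data.frames of class `event_table` with
#' columns `chrom`, `start_bp`, `end_bp` (0-based half-open),
#' `start_anchor`, `end_anchor` (one of `"MB"`, `"PTEL"`, `"CEN"`, `"QTEL"`),
#' `kind` and `level` (copy-level rank: single gain 1, further gain 2).
NULL

EVENT_KINDS <- c("LOSS", "GAIN", "FURTHER_GAIN", "AMP", "HOMDEL")

new_event_table <- function(df) {
  need <- c("chrom", "start_bp", "end_bp", "start_anchor", "end_anchor",
            "kind", "level")
  stopifnot(all(need %in% names(df)))
  stopifnot(all(df$kind %in% EVENT_KINDS))
  if (any(df$start_bp >= df$end_bp)) stop("event start must precede end")
  df <- df[order(match(df$chrom, c(as.character(1:22), "X")),
                 df$start_bp, df$end_bp, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

empty_event_table <- function() {
  new_event_table(data.frame(
    chrom = character(), start_bp = numeric(), end_bp = numeric(),
    start_anchor = character(), end_anchor = character(),
    kind = character(), level = integer(), stringsAsFactors = FALSE
  )[0, ])
}

#' Construct aberration events from coordinates or landmark tokens
#'
#' @param genome A `genome_model` used to resolve landmark tokens.
#' @param chrom Chromosome name(s).
#' @param start,end Endpoints: numeric Mb, or tokens `"PTEL"`, `"CEN"`,
#'   `"QTEL"`. Use `start = "PTEL", end = "QTEL"` for whole-chromosome events.
#' @param kind Event kind, one of `LOSS`, `GAIN`, `FURTHER_GAIN`, `AMP`,
#'   `HOMDEL` (case-insensitive; `"Further gain"` and `"Amplicon"` accepted).
#' @return An `event_table`.
#' @export
make_events <- function(genome, chrom, start, end, kind) {
  n <- max(length(chrom), length(start), length(end), length(kind))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.list(start), n)
  end <- rep_len(as.list(end), n)
  kind <- rep_len(kind, n)
  kind <- normalize_kind(kind)
  tok <- function(x) {
    vapply(x, function(v) {
      if (is.character(v) && toupper(v) %in% c("PTEL", "CEN", "QTEL"))
        toupper(v) else "MB"
    }, character(1))
  }
  start_anchor <- tok(start)
  end_anchor <- tok(end)
  start_bp <- vapply(seq_len(n), function(i)
    resolve_endpoint(genome, chrom[i], start[[i]]), numeric(1))
  end_bp <- vapply(seq_len(n), function(i)
    resolve_endpoint(genome, chrom[i], end[[i]]), numeric(1))
  new_event_table(data.frame(
    chrom = chrom, start_bp = start_bp, end_bp = end_bp,
    start_anchor = start_anchor, end_anchor = end_anchor,
    kind = kind, level = ifelse(kind == "FURTHER_GAIN", 2L, 1L),
    stringsAsFactors = FALSE
  ))
}

normalize_kind <- function(kind) {
  k <- toupper(gsub("[ -]", "_", trimws(kind)))
  k[k == "AMPLICON"] <- "AMP"
  k[k == "AMPLIFICATION"] <- "AMP"
  k[k == "HOMOZYGOUS_DELETION"] <- "HOMDEL"
  if (!all(k %in% EVENT_KINDS)) {
    stop("unknown event kind: ", paste(setdiff(k, EVENT_KINDS), collapse = ", "))
  }
  k
}

#' Snap event endpoints to arm landmarks
#'
#' Endpoints within `snap_tol_mb` of the p-terminus, centromere or
#' q-terminus are re-anchored to the corresponding token; an event anchored
#' PTEL-QTEL is a whole-chromosome event. Reported coordinates are at the
#' table dialect's one-decimal-Mb resolution, so sub-Mb jitter around a
#' landmark is below reporting resolution.
#'
#' @param events An `event_table`.
#' @param genome A `genome_model`.
#' @param snap_tol_mb Snap tolerance in Mb (default 1).
#' @return The `event_table` with anchors updated.
#' @export
snap_event_anchors <- function(events, genome, snap_tol_mb = 1) {
  if (!nrow(events)) return(events)
  tol <- snap_tol_mb * 1e6
  for (i in seq_len(nrow(events))) {
    row <- chrom_row(genome, events$chrom[i])
    s <- events$start_bp[i]; e <- events$end_bp[i]
    if (s <= tol) events$start_anchor[i] <- "PTEL"
    else if (abs(s - row$centromere_bp) <= tol) events$start_anchor[i] <- "CEN"
    if (e >= row$length_bp - tol) events$end_anchor[i] <- "QTEL"
    else if (abs(e - row$centromere_bp) <= tol) events$end_anchor[i] <- "CEN"
  }
  events
}

anchor_repr <- function(anchor, bp) {
  ifelse(anchor == "MB", sprintf("%.1f", bp / 1e6), anchor)
}

#' Canonical identity keys for events
#'
#' Two events with the same key are the same catalogue entry under exact
#' (zero-tolerance) matching: same chromosome, kind, copy level, and
#' endpoints token-for-token (numeric endpoints at one-decimal-Mb
#' resolution).
#'
#' @param events An `event_table`.
#' @return Character vector of keys.
#' @export
event_key <- function(events) {
  if (!nrow(events)) return(character(0))
  sprintf("%s|%s|%d|%s|%s", events$chrom, events$kind, events$level,
          anchor_repr(events$start_anchor, events$start_bp),
          anchor_repr(events$end_anchor, events$end_bp))
}

#' Format event positions in the reporting dialect
#'
#' Produces strings like `"153.8-q tel"`, `"p tel-13.2"`, `"Whole chr"`.
#'
#' @param events An `event_table`.
#' @return Character vector of position strings.
#' @export
format_event_position <- function(events) {
  if (!nrow(events)) return(character(0))
  pretty <- function(anchor, bp) {
    switch(anchor, PTEL = "p tel", CEN = "cen", QTEL = "q tel",
           sprintf("%.1f", bp / 1e6))
  }
  vapply(seq_len(nrow(events)), function(i) {
    if (events$start_anchor[i] == "PTEL" && events$end_anchor[i] == "QTEL") {
      "Whole chr"
    } else {
      paste0(pretty(events$start_anchor[i], events$start_bp[i]), "-",
             pretty(events$end_anchor[i], events$end_bp[i]))
    }
  }, character(1))
}

#' Convert called segments into aberration events
#'
#' Maximal runs of adjacent non-neutral segments with copy changes in the
#' same direction become one event; focal structure inside a run is emitted
#' as additional nested events:
#' * a gain run containing segments at two or more extra copies (relative to
#'   diploid, after cellularity correction) emits the base `GAIN` plus a
#'   nested `FURTHER_GAIN` on the higher-level interval;
#' * amplification-grade segments (`AMP` call, mean log2 ratio above the
#'   amplification threshold) emit `AMP` events on their own interval; an
#'   isolated amplicon emits only `AMP`;
#' * symmetric handling for losses, with homozygous-deletion-grade segments
#'   (`HOMDEL`) nested inside broader `LOSS` runs.
#'
#' Copy levels are estimated by inverting the mixture equation
#' `log2((c*cn + (1-c)*2)/2)` at the profile's cellularity `c` (assumed 1
#' when unknown), so a 40%-cellularity single-copy gain still counts one
#' extra copy.
#'
#' @param called_segments A data.frame of called segments (see
#'   [call_segments()]): `chrom`, `start_bp`, `end_bp`, `n_probes`,
#'   `mean_log2`, `call`.
#' @param genome A `genome_model`.
#' @param cellularity Tumour-cell fraction of the sample, or `NA` (treated
#'   as 1 for level estimation).
#' @param snap_tol_mb Landmark snap tolerance, see [snap_event_anchors()].
#' @param min_probes Smallest number of probes an emitted event may span
#'   (default 1: keep everything). A floor of a few probes suppresses
#'   single-probe noise spikes on noisy data.
#' @return An `event_table`.
#' @export
segments_to_events <- function(called_segments, genome, cellularity = NA_real_,
                               snap_tol_mb = 1, min_probes = 1) {
  segs <- called_segments
  out <- list()
  c_eff <- if (is.na(cellularity)) 1 else max(cellularity, 1e-3)
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    row <- chrom_row(genome, ch)
    if (any(s$start_bp < 0) || any(s$end_bp > row$length_bp)) {
      stop("segment outside chromosome bounds on ", ch)
    }
    cn_hat <- (2 * 2^s$mean_log2 - 2 * (1 - c_eff)) / c_eff
    delta <- as.integer(round(cn_hat)) - 2L
    delta[s$call == "NEUTRAL"] <- 0L
    delta[s$call %in% c("GAIN", "AMP")] <- pmax(1L, delta[s$call %in% c("GAIN", "AMP")])
    delta[s$call == "LOSS"] <- pmin(-1L, pmax(-1L, delta[s$call == "LOSS"]))
    delta[s$call == "HOMDEL"] <- -2L
    out[[length(out) + 1L]] <-
      layer_events(ch, s, delta, dir = +1L, extreme_call = "AMP",
                   min_probes = min_probes)
    out[[length(out) + 1L]] <-
      layer_events(ch, s, delta, dir = -1L, extreme_call = "HOMDEL",
                   min_probes = min_probes)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev) || !nrow(ev)) return(empty_event_table())
  ev <- new_event_table(ev)
  snap_event_anchors(ev, genome, snap_tol_mb = snap_tol_mb)
}

# Decompose one direction (gains dir=+1, losses dir=-1) of a chromosome's
# segment sequence into base events plus nested focal events.
layer_events <- function(ch, s, delta, dir, extreme_call, min_probes = 1) {
  d <- dir * delta
  active <- d >= 1L
  extreme <- s$call == extreme_call
  runs <- rle(active)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  rows <- list()
  emit <- function(i, j, kind, level) {
    if (sum(s$n_probes[i:j]) < min_probes) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = ch, start_bp = s$start_bp[i], end_bp = s$end_bp[j],
      start_anchor = "MB", end_anchor = "MB", kind = kind,
      level = as.integer(level), stringsAsFactors = FALSE
    )
  }
  base_kind <- if (dir > 0) "GAIN" else "LOSS"
  further_ok <- dir > 0  # the dialect has "further gain" but no further loss
  for (r in which(runs$values)) {
    i <- idx_start[r]; j <- idx_end[r]
    run_idx <- i:j
    all_extreme <- all(extreme[run_idx])
    if (!all_extreme) emit(i, j, base_kind, 1L)
    # extreme-grade (amplicon / homozygous-deletion) subruns
    ex <- rle(extreme[run_idx])
    ee <- cumsum(ex$lengths); es <- ee - ex$lengths + 1L
    for (q in which(ex$values)) {
      emit(run_idx[es[q]], run_idx[ee[q]],
           if (dir > 0) "AMP" else "HOMDEL", 1L)
    }
    # further-gain subruns: >= 2 extra copies, not amplification-grade,
    # strictly nested within the base run
    if (further_ok && !all_extreme) {
      hi <- d[run_idx] >= 2L & !extreme[run_idx]
      if (any(hi) && !all(hi)) {
        hx <- rle(hi)
        he <- cumsum(hx$lengths); hs <- he - hx$lengths + 1L
        for (q in which(hx$values)) {
          emit(run_idx[hs[q]], run_idx[he[q]], "FURTHER_GAIN", 2L)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Match events across the samples of one case into a unified catalogue
#'
#' Two events are the same catalogue entry iff they are on the same
#' chromosome, of the same kind and copy level, and their endpoints agree:
#' landmark-anchored endpoints must match token-for-token, numeric endpoints
#' must lie within `tol_mb`. Samples are processed in order and each event
#' either joins its (nearest, by summed endpoint distance) matching
#' catalogue entry or founds a new one; ties go to the earlier entry.
#'
#' @param event_lists Named list of `event_table`s, one per sample. Names are
#'   sample identifiers (`q<quadrant>_wk<week>`); alternatively supply
#'   `samples`.
#' @param samples Optional data.frame with columns `quadrant`, `week` (one
#'   row per element of `event_lists`).
#' @param case_id Case identifier carried into the result.
#' @param tol_mb Endpoint tolerance in Mb for numeric endpoints (default 1).
#' @return An object of class `event_matrix`: list with `case_id`, `events`
#'   (the unified catalogue, an `event_table`), `samples` (data.frame
#'   `sample_id`, `quadrant`, `week`) and `presence` (logical samples x
#'   events matrix).
#' @export
match_events <- function(event_lists, samples = NULL, case_id = "case",
                         tol_mb = 1) {
  stopifnot(is.list(event_lists), length(event_lists) >= 1, tol_mb >= 0)
  if (is.null(samples)) {
    ids <- names(event_lists)
    if (is.null(ids)) ids <- sprintf("s%d", seq_along(event_lists))
    qw <- parse_sample_id(ids)
    samples <- data.frame(sample_id = ids, quadrant = qw$quadrant,
                          week = qw$week, stringsAsFactors = FALSE)
  } else {
    samples$sample_id <- sprintf("q%d_wk%d", samples$quadrant, samples$week)
  }
  catalogue <- empty_event_table()
  for (si in seq_along(event_lists)) {
    ev <- event_lists[[si]]
    if (is.null(ev) || !nrow(ev)) next
    for (i in seq_len(nrow(ev))) {
      j <- find_catalogue_match(catalogue, ev[i, ], tol_mb)
      if (is.na(j)) {
        catalogue <- new_event_table(rbind(as.data.frame(catalogue),
                                           as.data.frame(ev[i, ])))
      }
    }
  }
  # fill presence against the final catalogue (entries re-sort as the
  # catalogue grows, so presence is resolved in a second pass)
  presence <- matrix(FALSE, nrow = nrow(samples), ncol = nrow(catalogue),
                     dimnames = list(samples$sample_id, event_key(catalogue)))
  for (si in seq_along(event_lists)) {
    ev <- event_lists[[si]]
    if (is.null(ev) || !nrow(ev)) next
    for (i in seq_len(nrow(ev))) {
      j <- find_catalogue_match(catalogue, ev[i, ], tol_mb)
      if (!is.na(j)) presence[si, j] <- TRUE
    }
  }
  structure(list(case_id = case_id, events = catalogue, samples = samples,
                 presence = presence),
            class = "event_matrix")
}

find_catalogue_match <- function(catalogue, ev, tol_mb) {
  if (!nrow(catalogue)) return(NA_integer_)
  tol <- tol_mb * 1e6 + 1  # +1 bp absorbs float rounding at exact tolerance
  cand <- which(
    catalogue$chrom == ev$chrom &
      catalogue$kind == ev$kind &
      catalogue$level == ev$level &
      catalogue$start_anchor == ev$start_anchor &
      catalogue$end_anchor == ev$end_anchor &
      (catalogue$start_anchor != "MB" |
         abs(catalogue$start_bp - ev$start_bp) <= tol) &
      (catalogue$end_anchor != "MB" |
         abs(catalogue$end_bp - ev$end_bp) <= tol)
  )
  if (!length(cand)) return(NA_integer_)
  if (length(cand) > 1) {
    d <- abs(catalogue$start_bp[cand] - ev$start_bp) +
      abs(catalogue$end_bp[cand] - ev$end_bp)
    cand <- cand[order(d, cand)]
  }
  cand[1]
}

parse_sample_id <- function(ids) {
  m <- regmatches(ids, regexec("^q([0-9]+)_wk([0-9]+)$", ids))
  q <- vapply(m, function(x) if (length(x) == 3) as.integer(x[2]) else NA_integer_,
              integer(1))
  w <- vapply(m, function(x) if (length(x) == 3) as.integer(x[3]) else NA_integer_,
              integer(1))
  list(quadrant = q, week = w)
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> case %s: %d samples x %d events\n",
              x$case_id, nrow(x$samples), nrow(x$events)))
  invisible(x)
}

#' Number of events differing between two samples of a case
#'
#' The symmetric (Hamming) difference between two samples' event presence
#' rows: events present in one sample but not the other. This is the
#' evolutionary distance used for clustering and tree building.
#'
#' @param matrix An `event_matrix`.
#' @param sample_a,sample_b Sample identifiers (`q<quadrant>_wk<week>`).
#' @return Integer count.
#' @export
pairwise_difference <- function(matrix, sample_a, sample_b) {
  rows <- presence_rows(matrix, c(sample_a, sample_b))
  sum(xor(rows[1, ], rows[2, ]))
}

presence_rows <- function(matrix, ids) {
  miss <- setdiff(ids, rownames(matrix$presence))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  matrix$presence[ids, , drop = FALSE]
}

#' All pairwise event distances of a case
#'
#' @param matrix An `event_matrix`.
#' @param extra_rows Optional named list of additional logical presence rows
#'   (e.g. an all-`FALSE` diploid normal).
#' @return A symmetric integer matrix of Hamming distances.
#' @export
event_distance_matrix <- function(matrix, extra_rows = NULL) {
  p <- matrix$presence
  if (!is.null(extra_rows)) {
    for (nm in names(extra_rows)) {
      p <- rbind(p, matrix(extra_rows[[nm]], nrow = 1,
                           dimnames = list(nm, colnames(p))))
    }
  }
  storage.mode(p) <- "integer"
  n <- nrow(p)
  d <- matrix(0L, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(p[i, ] != p[j, ])
  }
  d
}
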