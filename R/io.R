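extdata <- function(file) {
  path <- system.file("extdata", file, package = "cghclone")
  if (path == "") stop("packaged fixture not found: ", file)
  path
}

#' Load the packaged clinical/profile bookkeeping table
#'
#' The study's per-sample bookkeeping: for each case, quadrant and week,
#' whether a sample was taken, whether its array profile was abnormal, and
#' the histopathological tumour-cell percentage where scored. An empty
#' `abnormal` field means no sample (`NA`).
#'
#' @return List with `profiles` (case, quadrant, week, `abnormal` logical,
#'   `tumour_pct` raw string, `cellularity` numeric fraction or `NA`,
#'   `sample_id`) and `clinical` (per-case clinical fields).
#' @export
load_table1 <- function() {
  prof <- utils::read.csv(extdata("table1_profiles.csv"),
                          colClasses = "character")
  prof$quadrant <- as.integer(prof$quadrant)
  prof$week <- as.integer(prof$week)
  prof$abnormal <- ifelse(prof$abnormal == "", NA,
                          prof$abnormal == "T")
  prof$cellularity <- parse_tumour_pct(prof$tumour_pct)
  prof$sample_id <- sprintf("q%d_wk%d", prof$quadrant, prof$week)
  clin <- utils::read.csv(extdata("table1_clinical.csv"),
                          colClasses = "character")
  clin$survival_months <- as.numeric(clin$survival_months)
  clin$survival_censored <- clin$survival_censored == "T"
  list(profiles = prof, clinical = clin)
}

parse_tumour_pct <- function(x) {
  out <- rep(NA_real_, length(x))
  out[x == "<1"] <- 0.005
  num <- suppressWarnings(as.numeric(x))
  out[!is.na(num)] <- num[!is.na(num)] / 100
  out
}

#' Load the packaged rearrangement table
#'
#' Machine-readable transcription of the study's per-case aberration
#' events with quadrant presence per timepoint. Endpoints are Mb or the
#' tokens `PTEL`/`CEN`/`QTEL`; presence fields are semicolon-separated
#' quadrant lists; homogeneous (`Hom`) rows are present in every aberrant
#' sample of the case and carry empty presence fields.
#'
#' @return data.frame, one row per event.
#' @export
load_table2 <- function() {
  ev <- utils::read.csv(extdata("table2_events.csv"),
                        colClasses = "character")
  ev
}

#' Load the recruitment flow counts
#' @return List with `recruited`, `dropped_single_timepoint`, `no_chemo_rt`.
#' @export
load_recruitment <- function() {
  as.list(utils::read.csv(extdata("recruitment.csv")))
}

#' Evaluable cases after recruitment exclusions
#'
#' Patients who dropped out after collection at a single timepoint or who
#' did not receive chemoradiotherapy are excluded from the evaluable
#' cohort.
#'
#' @param recruited Number recruited (or a list with all three counts).
#' @param dropped_single_timepoint Drop-outs after a single timepoint.
#' @param no_chemo_rt Patients not treated with chemoradiotherapy.
#' @return Integer count of evaluable cases.
#' @export
cohort_filter <- function(recruited, dropped_single_timepoint = NULL,
                          no_chemo_rt = NULL) {
  if (is.list(recruited)) {
    dropped_single_timepoint <- recruited$dropped_single_timepoint
    no_chemo_rt <- recruited$no_chemo_rt
    recruited <- recruited$recruited
  }
  stopifnot(recruited >= 0, dropped_single_timepoint >= 0, no_chemo_rt >= 0)
  n <- recruited - dropped_single_timepoint - no_chemo_rt
  if (n < 0) stop("exclusions exceed the number recruited")
  as.integer(n)
}

#' Event matrix of a case from the packaged rearrangement table
#'
#' Builds the samples x events presence matrix directly from the packaged
#' tables: samples are the case's aberrant profiles (abnormal flag in the
#' bookkeeping table), heterogeneous rows are present in the listed
#' quadrants per timepoint, homogeneous rows in every aberrant sample.
#'
#' @param case_id Case identifier (`"CE01-02"`, `"CE01-09"`, `"CE01-13"`).
#' @param genome Optional `genome_model` for endpoint resolution.
#' @return List with the `event_matrix`, the per-sample `statuses` of the
#'   case, and `status_published` (the Hom/Het column as printed).
#' @export
fixture_case <- function(case_id, genome = NULL) {
  if (is.null(genome)) genome <- genome_model(n_probes = 50)
  t1 <- load_table1()$profiles
  t2 <- load_table2()
  st <- t1[t1$case == case_id & !is.na(t1$abnormal), , drop = FALSE]
  if (!nrow(st)) stop("unknown case or no samples: ", case_id)
  rows <- t2[t2$case == case_id, , drop = FALSE]
  if (!nrow(rows)) stop("no events tabulated for case ", case_id)
  events <- make_events(genome, chrom = rows$chrom,
                        start = endpoint_list(rows$start),
                        end = endpoint_list(rows$end),
                        kind = rows$type)
  # make_events sorts; recover the per-row mapping via keys
  key_in <- event_key(make_events_unsorted(genome, rows))
  col_of <- match(key_in, event_key(events))
  ab <- st[st$abnormal, , drop = FALSE]
  presence <- matrix(FALSE, nrow = nrow(ab), ncol = nrow(events),
                     dimnames = list(ab$sample_id, event_key(events)))
  for (r in seq_len(nrow(rows))) {
    j <- col_of[r]
    if (tolower(rows$status[r]) == "hom") {
      presence[, j] <- TRUE
    } else {
      for (wcol in c("wk0", "wk2", "wk5")) {
        quads <- strsplit(rows[[wcol]][r], ";")[[1]]
        if (!length(quads)) next
        week <- as.integer(sub("wk", "", wcol))
        sids <- sprintf("q%s_wk%d", quads, week)
        known <- sids %in% rownames(presence)
        if (!all(known)) {
          stop("presence refers to a non-aberrant sample in ", case_id,
               ": ", paste(sids[!known], collapse = ", "))
        }
        presence[sids, j] <- TRUE
      }
    }
  }
  status_published <- toupper(rows$status)[order(col_of)]
  mat <- structure(list(case_id = case_id, events = events,
                        samples = data.frame(sample_id = ab$sample_id,
                                             quadrant = ab$quadrant,
                                             week = ab$week,
                                             stringsAsFactors = FALSE),
                        presence = presence),
                   class = "event_matrix")
  list(matrix = mat, statuses = st, status_published = status_published)
}

endpoint_list <- function(x) {
  lapply(x, function(v) {
    if (v %in% c("PTEL", "CEN", "QTEL")) v else as.numeric(v)
  })
}

make_events_unsorted <- function(genome, rows) {
  # one-row-at-a-time keeps input order for key mapping
  do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
    make_events(genome, rows$chrom[i], endpoint_list(rows$start)[[i]],
                endpoint_list(rows$end)[[i]], rows$type[i])))
}

#' Write segments in SEG format
#'
#' Tab-delimited `ID chrom loc.start loc.end num.mark seg.mean`.
#'
#' @param segments data.frame of segments (optionally with an `ID` column).
#' @param path Output path.
#' @param id Sample identifier used when `segments` has no `ID` column.
#' @export
write_seg <- function(segments, path, id = "sample") {
  df <- data.frame(ID = if (is.null(segments$ID)) id else segments$ID,
                   chrom = segments$chrom,
                   loc.start = segments$start_bp,
                   loc.end = segments$end_bp,
                   num.mark = segments$n_probes,
                   seg.mean = sprintf("%.4f", segments$mean_log2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called segments or events as BED (0-based half-open)
#'
#' @param x Called segments (name = call, score = mean log2) or an
#'   `event_table` (name = kind).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "event_table")) {
    df <- data.frame(chrom = x$chrom, start = as.integer(x$start_bp),
                     end = as.integer(x$end_bp), name = x$kind, score = 0)
  } else {
    df <- data.frame(chrom = x$chrom, start = as.integer(x$start_bp),
                     end = as.integer(x$end_bp), name = x$call,
                     score = sprintf("%.4f", x$mean_log2))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a case tree in Newick format (rooted at the diploid outgroup)
#' @param case_tree A `case_tree`.
#' @param path Output path.
#' @export
write_newick <- function(case_tree, path) {
  ape::write.tree(case_tree$rooted, file = path)
  invisible(path)
}

#' Write a heterogeneity report in the rearrangement-table layout
#' @param het A `het_call`.
#' @param path Output path.
#' @param case_id Case label for the first column.
#' @export
write_het_report <- function(het, path, case_id = "case") {
  df <- data.frame(case = case_id, chrom = het$chrom,
                   position = format_event_position(
                     new_event_table(as.data.frame(het)[, 1:7])),
                   type = het$kind, status = het$status,
                   present_in = het$present_in)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a subpopulation map as a CSV grid
#' @param map A `subpop_map`.
#' @param path Output path.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(unclass(map)), path, row.names = TRUE)
  invisible(path)
}

#' Write a trajectory report as JSON
#' @param calls A `trajectory_call`.
#' @param path Output path.
#' @export
write_trajectory_json <- function(calls, path) {
  jsonlite::write_json(list(per_quadrant = calls$per_quadrant,
                            residual_disease_week5 = calls$residual_disease_week5,
                            resistant_label = calls$resistant_label),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
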