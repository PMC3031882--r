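MAP_WEEKS <- c(0L, 2L, 5L)

#' Build the quadrant-by-timepoint subpopulation map
#'
#' A 4 x 3 grid (quadrants 1-4, weeks 0/2/5): the subpopulation label where
#' an aberrant sample was profiled, `NORMAL` where a sample exists but its
#' profile is not abnormal (low tumour content), `MISSING` where no sample
#' was taken.
#'
#' @param statuses Profile-status data.frame for every existing sample of
#'   the case: `quadrant`, `week`, `abnormal` (plus `sample_id`).
#' @param labels Subpopulation labels of the aberrant samples.
#' @param case_id Case identifier.
#' @return Object of class `subpop_map`: character matrix with rownames
#'   `q1..q4` and colnames `wk0, wk2, wk5`.
#' @export
build_map <- function(statuses, labels, case_id = "case") {
  grid <- matrix("MISSING", nrow = 4, ncol = length(MAP_WEEKS),
                 dimnames = list(paste0("q", 1:4), paste0("wk", MAP_WEEKS)))
  if (!is.null(statuses) && nrow(statuses)) {
    if (is.null(statuses$sample_id)) {
      statuses$sample_id <- sprintf("q%d_wk%d", statuses$quadrant,
                                    statuses$week)
    }
    for (r in seq_len(nrow(statuses))) {
      q <- statuses$quadrant[r]
      w <- match(statuses$week[r], MAP_WEEKS)
      if (is.na(w)) next
      if (!statuses$abnormal[r]) {
        grid[q, w] <- "NORMAL"
      } else {
        lab <- labels[statuses$sample_id[r]]
        grid[q, w] <- if (is.na(lab)) "NORMAL" else unname(lab)
      }
    }
  }
  structure(grid, case_id = case_id, class = c("subpop_map", "matrix"))
}

#' @export
print.subpop_map <- function(x, ...) {
  cat(sprintf("<subpop_map> case %s\n", attr(x, "case_id")))
  print(unclass(x))
  invisible(x)
}

is_label <- function(x) !(x %in% c("NORMAL", "MISSING"))

#' Classify per-quadrant subpopulation trajectories
#'
#' Compares each quadrant's first observed state with its end-of-treatment
#' (week 5) state: `CLEARANCE` (subpopulation to normal profile),
#' `PERSISTENCE` (same subpopulation), `REPLACEMENT` (one subpopulation
#' replaced by another), `NO_TUMOUR` (normal throughout), `EMERGENCE`
#' (normal to subpopulation). A quadrant with no week-5 sample gets no call
#' (`NA`): missing cores are not imputed. Week-2 samples inform the map but
#' trajectory classes are defined on the week 0 -> 5 endpoints.
#'
#' @param map A `subpop_map`.
#' @return Object of class `trajectory_call`: list with `per_quadrant`
#'   (data.frame `quadrant`, `from`, `to`, `class`),
#'   `residual_disease_week5`, `resistant_label` (the unique label present
#'   at week 5, if any) and `week5_conflict` (TRUE when several distinct
#'   labels persist).
#' @export
call_trajectories <- function(map) {
  per_q <- data.frame(quadrant = 1:4, from = NA_character_,
                      to = NA_character_, class = NA_character_,
                      stringsAsFactors = FALSE)
  for (q in 1:4) {
    cells <- map[q, ]
    to <- cells["wk5"]
    if (to == "MISSING") next
    obs <- cells[cells != "MISSING"]
    if (!length(obs)) next
    from <- obs[1]
    per_q$from[q] <- from
    per_q$to[q] <- to
    per_q$class[q] <-
      if (is_label(from) && !is_label(to)) "CLEARANCE"
      else if (is_label(from) && from == to) "PERSISTENCE"
      else if (is_label(from) && is_label(to)) "REPLACEMENT"
      else if (!is_label(from) && is_label(to)) "EMERGENCE"
      else "NO_TUMOUR"
  }
  wk5 <- map[, "wk5"]
  persist <- wk5[is_label(wk5)]
  structure(list(per_quadrant = per_q,
                 residual_disease_week5 = length(persist) > 0,
                 resistant_label = if (length(unique(persist)) == 1)
                   unname(unique(persist)) else NA_character_,
                 week5_conflict = length(unique(persist)) > 1),
            class = "trajectory_call")
}

#' @export
print.trajectory_call <- function(x, ...) {
  cat("<trajectory_call>\n")
  print(x$per_quadrant)
  cat(sprintf("residual disease at week 5: %s\n",
              x$residual_disease_week5))
  invisible(x)
}

#' Ground-truth subpopulation map of a simulated study
#'
#' Derives the map the analysis should recover: per (quadrant, week), the
#' dominant detectable clone, `NORMAL` when no clone is detectable, and
#' `MISSING` for unsampled cells.
#'
#' @param truth A `spatial_truth` covering the sampled weeks.
#' @return A `subpop_map` whose labels are clone ids.
#' @export
truth_map <- function(truth) {
  grid <- matrix("MISSING", nrow = 4, ncol = length(MAP_WEEKS),
                 dimnames = list(paste0("q", 1:4), paste0("wk", MAP_WEEKS)))
  for (r in seq_len(nrow(truth$grid))) {
    if (!truth$grid$present[r]) next
    w <- match(truth$grid$week[r], MAP_WEEKS)
    q <- truth$grid$quadrant[r]
    det <- truth$detectable[r, ]
    if (!any(det)) {
      grid[q, w] <- "NORMAL"
    } else {
      f <- truth$fractions[r, ]
      f[!det] <- 0
      grid[q, w] <- names(which.max(f))
    }
  }
  structure(grid, case_id = "truth", class = c("subpop_map", "matrix"))
}

#' Score recovered trajectories against simulation truth
#'
#' @param truth A `spatial_truth`.
#' @param calls A `trajectory_call` from the analysis.
#' @return List with `confusion` (true x called class table), `n_scored`
#'   and `accuracy` over quadrants where both sides make a call.
#' @export
selection_summary <- function(truth, calls) {
  tmap <- truth_map(truth)
  tcalls <- call_trajectories(tmap)
  truth_cls <- tcalls$per_quadrant$class
  called_cls <- calls$per_quadrant$class
  ok <- !is.na(truth_cls) & !is.na(called_cls)
  confusion <- table(truth = truth_cls[ok], called = called_cls[ok])
  list(confusion = confusion, n_scored = sum(ok),
       accuracy = if (any(ok)) mean(truth_cls[ok] == called_cls[ok]) else NA_real_)
}
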