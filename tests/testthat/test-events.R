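hg <- genome_model(n_probes = 50)

called <- function(chrom, start_mb, end_mb, n, mean) {
  data.frame(chrom = chrom, start_bp = start_mb * 1e6, end_bp = end_mb * 1e6,
             n_probes = n, mean_log2 = mean, stringsAsFactors = FALSE)
}

test_that("event construction, formatting and keys use the arm dialect", {
  ev <- make_events(hg, chrom = c("9", "3", "17"),
                    start = list("PTEL", 153.8, "PTEL"),
                    end = list(13.2, "QTEL", "QTEL"),
                    kind = c("Loss", "Gain", "Gain"))
  expect_equal(format_event_position(ev),
               c("153.8-q tel", "p tel-13.2", "Whole chr"))
  expect_equal(ev$kind, c("GAIN", "LOSS", "GAIN"))
  expect_match(event_key(ev)[1], "^3\\|GAIN\\|1\\|153.8\\|QTEL$")
  expect_error(make_events(hg, "1", 10, 5, "GAIN"), "precede")
  expect_error(make_events(hg, "1", 0, 5, "SPLICE"), "unknown event kind")
})

test_that("a terminal gain is emitted QTEL-anchored", {
  # gain from 141.6 Mb to the chromosome-3 end
  segs <- call_segments(rbind(called("3", 0, 141.6, 40, 0),
                              called("3", 141.6, 199.5017, 15, 0.58)))
  ev <- segments_to_events(segs, hg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "GAIN")
  expect_equal(ev$start_anchor, "MB")
  expect_equal(ev$end_anchor, "QTEL")
  expect_equal(format_event_position(ev), "141.6-q tel")
})

test_that("neutral-only profiles yield no events", {
  segs <- call_segments(rbind(called("1", 0, 120, 40, 0.02),
                              called("1", 120, 247.2, 40, -0.05)))
  expect_equal(nrow(segments_to_events(segs, hg)), 0)
})

test_that("nested copy levels split into base and focal events", {
  # gain run with an inner double gain: GAIN over the run + FURTHER_GAIN
  segs <- call_segments(rbind(called("11", 0, 75.1, 30, 0),
                              called("11", 75.1, 98.9, 10, log2(3 / 2)),
                              called("11", 98.9, 104.4, 4, log2(4 / 2)),
                              called("11", 104.4, 110, 3, log2(3 / 2)),
                              called("11", 110, 134.45, 10, 0)))
  ev <- segments_to_events(segs, hg)
  expect_setequal(ev$kind, c("GAIN", "FURTHER_GAIN"))
  fg <- ev[ev$kind == "FURTHER_GAIN", ]
  expect_equal(c(fg$start_bp, fg$end_bp), c(98.9e6, 104.4e6))
  expect_equal(ev$start_bp[ev$kind == "GAIN"], 75.1e6)
  expect_equal(ev$end_bp[ev$kind == "GAIN"], 110e6)

  # an isolated amplicon emits AMP alone; inside a broader gain, both
  segs2 <- call_segments(rbind(called("17", 0, 28.5, 10, 0),
                               called("17", 28.5, 29.7, 3, 2.1),
                               called("17", 29.7, 78.77, 20, 0)))
  ev2 <- segments_to_events(segs2, hg)
  expect_equal(ev2$kind, "AMP")
  segs3 <- call_segments(rbind(called("17", 0, 28.5, 10, log2(3 / 2)),
                               called("17", 28.5, 29.7, 3, 2.1),
                               called("17", 29.7, 78.77, 20, log2(3 / 2))))
  ev3 <- segments_to_events(segs3, hg)
  expect_setequal(ev3$kind, c("GAIN", "AMP"))

  # symmetric for deletions: homozygous-deletion-grade nested in a loss
  segs4 <- call_segments(rbind(called("4", 0, 50, 10, -1),
                               called("4", 50, 60, 4, -4),
                               called("4", 60, 100, 10, -1),
                               called("4", 100, 191.27, 10, 0)))
  ev4 <- segments_to_events(segs4, hg)
  expect_setequal(ev4$kind, c("LOSS", "HOMDEL"))
})

test_that("copy levels are cellularity-corrected", {
  # at 40% cellularity a single-copy gain renders ~0.263; with the
  # cellularity supplied the inferred level is one extra copy, not zero
  segs <- call_segments(rbind(called("2", 0, 100, 30, 0),
                              called("2", 100, 180, 25, log2(2.4 / 2)),
                              called("2", 180, 242.95, 20, 0)))
  ev <- segments_to_events(segs, hg, cellularity = 0.4)
  expect_equal(ev$kind, "GAIN")
  expect_equal(ev$level, 1L)
})

test_that("the probe floor suppresses tiny events", {
  segs <- call_segments(rbind(called("5", 0, 90, 40, 0),
                              called("5", 90, 93, 2, 0.9),
                              called("5", 93, 180.8, 40, 0)))
  expect_equal(nrow(segments_to_events(segs, hg, min_probes = 5)), 0)
  expect_equal(nrow(segments_to_events(segs, hg)), 1)
})

test_that("matching unifies identical lists and separates distinct endpoints", {
  a <- make_events(hg, c("3", "11"), list(55.8, 94.8), list("CEN", "QTEL"),
                   c("LOSS", "LOSS"))
  m <- match_events(list(q1_wk0 = a, q2_wk0 = a))
  expect_equal(nrow(m$events), 2)
  expect_true(all(m$presence))
  expect_equal(pairwise_difference(m, "q1_wk0", "q2_wk0"), 0)

  # two terminal losses 9.5 Mb apart stay distinct at 1 Mb tolerance
  b1 <- make_events(hg, "11", 85.3, "QTEL", "LOSS")
  b2 <- make_events(hg, "11", 94.8, "QTEL", "LOSS")
  m2 <- match_events(list(q1_wk0 = b1, q2_wk0 = b2), tol_mb = 1)
  expect_equal(nrow(m2$events), 2)
  expect_equal(pairwise_difference(m2, "q1_wk0", "q2_wk0"), 2)

  # sub-tolerance jitter merges into one catalogue entry
  c1 <- make_events(hg, "5", 10.0, 60.0, "GAIN")
  c2 <- make_events(hg, "5", 10.6, 59.5, "GAIN")
  m3 <- match_events(list(q1_wk0 = c1, q2_wk0 = c2), tol_mb = 1)
  expect_equal(nrow(m3$events), 1)
  expect_equal(pairwise_difference(m3, "q1_wk0", "q2_wk0"), 0)

  # level-aware: a further gain never matches a plain gain
  d1 <- make_events(hg, "19", 30, 51.5, "GAIN")
  d2 <- make_events(hg, "19", 30, 51.5, "Further gain")
  m4 <- match_events(list(q1_wk0 = d1, q2_wk0 = d2))
  expect_equal(nrow(m4$events), 2)
})

test_that("ambiguous matches resolve to the nearest catalogue entry", {
  # two catalogue entries 2.2 Mb apart (beyond tolerance of each other),
  # plus an event within tolerance of both
  e1 <- make_events(hg, "7", 10, 50, "GAIN")
  e2 <- make_events(hg, "7", 12.2, 52.2, "GAIN")
  mid <- make_events(hg, "7", 11, 51, "GAIN")
  m <- match_events(list(q1_wk0 = e1, q2_wk0 = e2, q3_wk0 = mid),
                    tol_mb = 2)
  expect_equal(nrow(m$events), 2)
  # the middle event lands on the 10/50 entry (summed distance 2.0 Mb
  # vs 2.4 Mb)
  j <- which(m$events$start_bp == 10e6)
  expect_true(m$presence["q3_wk0", j])
  expect_equal(sum(m$presence["q3_wk0", ]), 1)
})

test_that("pairwise difference is a metric on presence rows", {
  fx <- fixture_case("CE01-02")
  d <- event_distance_matrix(fx$matrix)
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j])
  }
})

test_that("simulated events survive the full noiseless round trip", {
  for (s in c(31, 32)) {
    cfg <- sim_config(n_trunk = 2, n_lineages = 2, n_branch = 3,
                      survival = c(1, 1), cellularity_range = c(1, 1),
                      noise_sd = 0, weeks = 0, n_probes = 1200,
                      min_event_mb = 25, min_event_probes = 10,
                      buffer_probes = 6, seed = s)
    sim <- simulate_study(cfg)
    res <- analyze_profiles(sim$profiles, sim$genome,
                            pipeline_config(n_perm = 500, seed = s,
                                            snap_tol_mb = 2))
    truth <- snap_event_anchors(truth_event_catalogue(sim$clones),
                                sim$genome, 2)
    expect_setequal(event_key(res$matrix$events), event_key(truth))
  }
})
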