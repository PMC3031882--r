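test_that("map cells are exactly one of label, NORMAL, MISSING", {
  expect_true(all(build_map(NULL, character(0)) == "MISSING"))
  statuses <- data.frame(quadrant = c(1, 1, 2), week = c(0, 5, 0),
                         abnormal = c(TRUE, FALSE, TRUE))
  labels <- c(q1_wk0 = "A", q2_wk0 = "B")
  map <- build_map(statuses, labels, "toy")
  expect_equal(unname(map["q1", ]), c("A", "MISSING", "NORMAL"))
  expect_equal(unname(map["q2", "wk0"]), "B")
  expect_true(all(map %in% c("A", "B", "NORMAL", "MISSING")))
})

test_that("single-quadrant disease clearing by week 5 is called correctly", {
  # one aberrant quadrant pre-treatment, everything normal at week 5
  statuses <- data.frame(quadrant = c(1, 2, 3, 4, 1, 2, 3, 4),
                         week = c(rep(0, 4), rep(5, 4)),
                         abnormal = c(FALSE, FALSE, FALSE, TRUE,
                                      rep(FALSE, 4)))
  map <- build_map(statuses, c(q4_wk0 = "A"), "CE01-01-like")
  traj <- call_trajectories(map)
  expect_equal(traj$per_quadrant$class, c("NO_TUMOUR", "NO_TUMOUR",
                                          "NO_TUMOUR", "CLEARANCE"))
  expect_false(traj$residual_disease_week5)
  expect_true(is.na(traj$resistant_label))
})

test_that("persistence, replacement and missing-core rules follow the map", {
  map <- structure(matrix(c("A", "MISSING", "A",
                            "A", "MISSING", "B",
                            "B", "MISSING", "MISSING",
                            "NORMAL", "MISSING", "A"),
                          nrow = 4, byrow = TRUE,
                          dimnames = list(paste0("q", 1:4),
                                          c("wk0", "wk2", "wk5"))),
                   case_id = "toy", class = c("subpop_map", "matrix"))
  traj <- call_trajectories(map)
  expect_equal(traj$per_quadrant$class,
               c("PERSISTENCE", "REPLACEMENT", NA, "EMERGENCE"))
  expect_true(traj$residual_disease_week5)
  expect_true(traj$week5_conflict)  # A and B both persist
  expect_true(is.na(traj$resistant_label))
})

test_that("simulation truth maps mark undetectable clones as normal", {
  cfg <- sim_config(seed = 3, n_probes = 400, survival = c(0, 1),
                    cellularity_range = c(0.8, 0.8), weeks = c(0, 5))
  sim <- simulate_study(cfg)
  tm <- truth_map(sim$truth)
  # sensitive lineage quadrants cleared, resistant ones persist
  cleared <- tm[, "wk0"] != tm[, "wk5"] & tm[, "wk5"] == "NORMAL"
  persist <- tm[, "wk0"] == tm[, "wk5"] & tm[, "wk5"] != "NORMAL"
  expect_equal(sum(cleared), 2)
  expect_equal(sum(persist), 2)
})

test_that("selection scoring matches the pipeline on a clean simulation", {
  cfg <- sim_config(seed = 8, n_probes = 1500, survival = c(0, 0.6),
                    cellularity_range = c(1, 1), noise_sd = 0,
                    weeks = c(0, 5), min_event_mb = 18,
                    min_event_probes = 8, buffer_probes = 6)
  sim <- simulate_study(cfg)
  res <- analyze_profiles(sim$profiles, sim$genome,
                          pipeline_config(n_perm = 500, seed = 8))
  sel <- selection_summary(sim$truth, res$trajectories)
  expect_equal(sel$accuracy, 1)
  expect_equal(sel$n_scored, 4)
  # survival 1 for every clone: nothing may be called CLEARANCE
  wk5 <- evolve_fractions(simulate_truth_week0(sim$clones, cfg),
                          c(L1 = 1, L2 = 1), week = 5)
  truth_all <- sim$truth
  truth_all$grid <- rbind(sim$truth$grid[sim$truth$grid$week == 0, ], wk5$grid)
  truth_all$fractions <- rbind(
    sim$truth$fractions[sim$truth$grid$week == 0, ], wk5$fractions)
  truth_all$detectable <- rbind(
    sim$truth$detectable[sim$truth$grid$week == 0, ], wk5$detectable)
  tcalls <- call_trajectories(truth_map(truth_all))
  expect_false("CLEARANCE" %in% tcalls$per_quadrant$class)
})
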