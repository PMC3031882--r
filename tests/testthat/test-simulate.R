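test_that("an eventless configuration yields a flat diploid clone", {
  gm <- genome_model(200)
  cfg <- sim_config(n_trunk = 0, n_lineages = 1, n_branch = 0, seed = 1)
  clones <- simulate_clone_phylogeny(cfg, gm)
  expect_setequal(names(clones$clones), c("ROOT", "L1"))
  expect_equal(nrow(clones$clones$L1$events), 0)
  expect_true(all(clone_copy_number(clones, "L1", gm) == 2L))
})

test_that("lineages share exactly the trunk and keep private branch events", {
  gm <- genome_model(1000)
  cfg <- sim_config(n_trunk = 3, n_lineages = 2, n_branch = 4,
                    min_event_mb = 20, min_event_probes = 3, seed = 7)
  clones <- simulate_clone_phylogeny(cfg, gm)
  trunk <- event_key(clones$clones$ROOT$events)
  k1 <- event_key(clones$clones$L1$events)
  k2 <- event_key(clones$clones$L2$events)
  expect_length(trunk, 3)
  expect_setequal(intersect(k1, k2), trunk)
  expect_length(setdiff(k1, trunk), 4)
  expect_length(setdiff(k2, trunk), 4)
  expect_true(all(trunk %in% k1) && all(trunk %in% k2))
})

test_that("the cervical preset places its trunk events in every leaf", {
  gm <- genome_model(3000)
  cfg <- sim_config(n_trunk = 2, n_lineages = 2, n_branch = 2,
                    min_event_mb = 20, min_event_probes = 3,
                    trunk_preset = cervical_preset(gm), seed = 3)
  clones <- simulate_clone_phylogeny(cfg, gm)
  for (l in c("L1", "L2")) {
    ev <- clones$clones[[l]]$events
    gain3q <- ev[ev$chrom == "3" & ev$kind == "GAIN" &
                   ev$end_anchor == "QTEL", , drop = FALSE]
    expect_equal(nrow(gain3q), 1)
    expect_lt(abs(gain3q$start_bp - 153.8e6), 2e6)  # probe-snapped
    expect_true(any(ev$chrom == "11" & ev$kind == "LOSS" &
                      ev$end_anchor == "QTEL"))
  }
})

test_that("event placement fails loudly when the genome cannot hold the events", {
  gm <- toy_genome(20, length_bp = 20e6)
  cfg <- sim_config(n_trunk = 10, n_lineages = 2, n_branch = 10,
                    min_event_mb = 5, min_event_probes = 5, seed = 1)
  expect_error(simulate_clone_phylogeny(cfg, gm), "too small")
})

test_that("survival of 1 leaves the truth unchanged", {
  gm <- genome_model(300)
  cfg <- sim_config(seed = 2, n_probes = 300)
  clones <- simulate_clone_phylogeny(cfg, gm)
  wk0 <- simulate_truth_week0(clones, cfg)
  wk5 <- evolve_fractions(wk0, c(L1 = 1, L2 = 1), week = 5)
  expect_equal(wk5$fractions, wk0$fractions)
  expect_equal(wk5$grid$cellularity, wk0$grid$cellularity)
})

test_that("total clearance of the dominant clone leaves the minor clone at fraction 1", {
  gm <- genome_model(300)
  cfg <- sim_config(seed = 2, n_probes = 300, minor_fraction = 0.2)
  clones <- simulate_clone_phylogeny(cfg, gm)
  wk0 <- simulate_truth_week0(clones, cfg)
  wk5 <- evolve_fractions(wk0, c(L1 = 0, L2 = 1), week = 5)
  q1 <- which(wk5$grid$quadrant == 1)  # L1-dominant at week 0
  expect_equal(unname(wk5$fractions[q1, "L2"]), 1)
  expect_equal(unname(wk5$fractions[q1, "L1"]), 0)
  # tumour compartment shrank: cellularity strictly lower
  expect_lt(wk5$grid$cellularity[q1], wk0$grid$cellularity[q1])
})

test_that("near-clearance under treatment flips dominance to the minor clone", {
  # dominant clone survival 0.01 vs minor 0.3: the formerly minor clone
  # dominates the residual tumour, the old dominant drops below detection
  gm <- genome_model(300)
  cfg <- sim_config(seed = 5, n_probes = 300, minor_fraction = 0.2,
                    detect_floor = 0.10, cellularity_range = c(0.8, 0.9))
  clones <- simulate_clone_phylogeny(cfg, gm)
  wk0 <- simulate_truth_week0(clones, cfg)
  wk2 <- evolve_fractions(wk0, c(L1 = 0.01, L2 = 0.3), week = 2)
  q1 <- which(wk2$grid$quadrant == 1)
  expect_gt(wk2$fractions[q1, "L2"], 0.8)
  expect_false(wk2$detectable[q1, "L1"])
  expect_equal(unname(rowSums(wk2$fractions)), rep(1, 4))
})

test_that("rendering follows the closed-form mixture equation", {
  gm <- toy_genome(60)
  cfg <- sim_config(n_trunk = 1, n_lineages = 1, n_branch = 0,
                    n_probes = 60, min_event_mb = 20, min_event_probes = 10,
                    p_whole = 0, p_further = 0,
                    kind_weights = c(GAIN = 1, LOSS = 0, AMP = 0, HOMDEL = 0),
                    noise_sd = 0, seed = 4)
  clones <- simulate_clone_phylogeny(cfg, gm)
  truth <- simulate_truth_week0(clones, cfg)
  ev <- clones$clones$L1$events
  in_event <- gm$probes$pos_bp >= ev$start_bp & gm$probes$pos_bp < ev$end_bp

  # pure stroma: exactly zero everywhere
  truth$grid$cellularity <- rep(0, 4)
  p0 <- render_probe_data(truth, clones, gm, noise_sd = 0, seed = 1)
  expect_true(all(p0$q1_wk0$probes$log2_ratio == 0))

  # pure tumour, single-copy gain: log2(3/2) inside, 0 outside
  truth$grid$cellularity <- rep(1, 4)
  p1 <- render_probe_data(truth, clones, gm, noise_sd = 0, seed = 1)
  expect_equal(unique(p1$q1_wk0$probes$log2_ratio[in_event]), log2(3 / 2))
  expect_equal(unique(p1$q1_wk0$probes$log2_ratio[!in_event]), 0)

  # 40% cellularity: log2(2.4/2) ~ 0.263 inside the event
  truth$grid$cellularity <- rep(0.4, 4)
  p4 <- render_probe_data(truth, clones, gm, noise_sd = 0, seed = 1)
  expect_equal(unique(p4$q1_wk0$probes$log2_ratio[in_event]), log2(2.4 / 2))
})

test_that("the seed fully determines the simulated study", {
  cfg <- sim_config(seed = 9, n_probes = 500)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(lapply(s1$profiles, function(p) p$probes$log2_ratio),
                   lapply(s2$profiles, function(p) p$probes$log2_ratio))
  expect_identical(s1$truth$fractions, s2$truth$fractions)
})

test_that("fixtures round-trip through disk byte-identically", {
  cfg <- sim_config(seed = 9, n_probes = 400)
  sim <- simulate_study(cfg)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  write_fixture(sim$profiles, sim$truth, sim$clones, d1)
  write_fixture(sim$profiles, sim$truth, sim$clones, d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(d2, basename(f1)))))
  # probe tables read back losslessly (to the written precision)
  back <- read_probe_table(file.path(d1, "SIM_q1_wk0.tsv"))
  expect_equal(back$quadrant, 1)
  expect_equal(back$week, 0)
  expect_equal(back$probes$log2_ratio,
               round(sim$profiles$q1_wk0$probes$log2_ratio, 6))
  manifest <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_setequal(names(manifest$clones), names(sim$clones$clones))
})
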