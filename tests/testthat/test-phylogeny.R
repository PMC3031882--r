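hg <- genome_model(n_probes = 50)
new_event_table <- cghclone:::new_event_table

three_leaf_matrix <- function(t = 3, a = 2, b = 4) {
  trunk <- make_events(hg, as.character(seq_len(t)), 10, 40, "GAIN")
  pa <- make_events(hg, as.character(4 + seq_len(a)), 60, 90, "LOSS")
  pb <- make_events(hg, as.character(10 + seq_len(b)), 60, 90, "LOSS")
  ga <- new_event_table(rbind(as.data.frame(trunk), as.data.frame(pa)))
  gb <- new_event_table(rbind(as.data.frame(trunk), as.data.frame(pb)))
  match_events(list(q1_wk0 = ga, q2_wk0 = gb))
}

test_that("NJ on a 3-leaf additive matrix recovers the closed-form branches", {
  t <- 3; a <- 2; b <- 4
  m <- three_leaf_matrix(t, a, b)
  tree <- build_tree(m)
  cop <- tree_path_lengths(tree)
  # three-point formulas: NORMAL-junction = t, junction-leaves = a and b
  expect_equal(cop["q1_wk0", "q2_wk0"], a + b)
  expect_equal(cop["NORMAL", "q1_wk0"], t + a)
  expect_equal(cop["NORMAL", "q2_wk0"], t + b)
  ed <- setNames(tree$tree$edge.length,
                 c(tree$tree$tip.label,
                   rep(NA, tree$tree$Nnode))[tree$tree$edge[, 2]])
  expect_equal(unname(ed["NORMAL"]), t)
  expect_equal(unname(ed["q1_wk0"]), a)
  expect_equal(unname(ed["q2_wk0"]), b)
})

test_that("identical samples form a zero-length cherry", {
  ev <- make_events(hg, c("1", "2"), 10, 40, "GAIN")
  m <- match_events(list(q1_wk0 = ev, q2_wk0 = ev))
  tree <- build_tree(m)
  cop <- tree_path_lengths(tree)
  expect_equal(cop["q1_wk0", "q2_wk0"], 0)
  expect_equal(cop["NORMAL", "q1_wk0"], 2)
})

test_that("trees require at least one aberrant sample", {
  m <- three_leaf_matrix()
  st <- data.frame(sample_id = m$samples$sample_id, abnormal = FALSE)
  expect_error(build_tree(m, statuses = st), "at least 2 leaves")
})

test_that("negative branch lengths are clamped with the deficit moved to the sibling", {
  m <- three_leaf_matrix()
  tree <- build_tree(m)$tree
  e <- which(tree$edge[, 2] == match("NORMAL", tree$tip.label))
  parent <- tree$edge[e, 1]
  sib <- setdiff(which(tree$edge[, 1] == parent), e)[1]
  before <- tree$edge.length[e] + tree$edge.length[sib]
  tree$edge.length[e] <- -1
  fixed <- cghclone:::clamp_negative_edges(tree)
  expect_true(all(fixed$edge.length >= 0))
  expect_equal(fixed$edge.length[e], 0)
  expect_equal(fixed$edge.length[e] + fixed$edge.length[sib],
               tree$edge.length[sib] - 1)
})

test_that("leaf-to-leaf path lengths reproduce additive event distances", {
  suite <- additivity_suite(n_runs = 8, base_seed = 900)
  expect_true(all(suite$max_deviation < 1e-9))
})

test_that("trunk inference returns the intersection of consensus genotypes", {
  cfg <- sim_config(n_trunk = 3, n_lineages = 3, n_branch = 4,
                    n_probes = 600, min_event_mb = 20, min_event_probes = 3,
                    seed = 44)
  clones <- simulate_clone_phylogeny(cfg, genome_model(n_probes = 600))
  m <- clone_event_matrix(clones)
  labels <- setNames(LETTERS[1:3], m$samples$sample_id)
  rep <- infer_early_events(m, labels)
  trunk_keys <- event_key(new_event_table(
    as.data.frame(rep)[rep$class == "TRUNK", 1:7]))
  expect_setequal(trunk_keys, event_key(clones$clones$ROOT$events))
  expect_true(all(rep$class %in% c("TRUNK", "BRANCH")))
})

test_that("a single subpopulation makes every event trunk", {
  ev <- make_events(hg, c("1", "2"), 10, 40, "GAIN")
  m <- match_events(list(q1_wk0 = ev, q2_wk0 = ev))
  labels <- setNames(c("A", "A"), m$samples$sample_id)
  rep <- infer_early_events(m, labels)
  expect_true(all(rep$class == "TRUNK"))
})

test_that("an empty trunk warns about contradicting monoclonality", {
  a <- make_events(hg, "1", 10, 40, "GAIN")
  b <- make_events(hg, "2", 10, 40, "LOSS")
  m <- match_events(list(q1_wk0 = a, q2_wk0 = b))
  labels <- setNames(c("A", "B"), m$samples$sample_id)
  expect_warning(infer_early_events(m, labels), "monoclonal")
})

test_that("chromosome ordering is a faithful re-projection of the early report", {
  fx <- fixture_case("CE01-02")
  labels <- assign_subpopulations(fx$matrix)
  rep <- infer_early_events(fx$matrix, labels)
  chr11 <- order_chromosome_events(rep, "11")
  expect_equal(chr11$chrom, rep("11", 3))
  expect_true(all(diff(chr11$start_bp) >= 0))
  expect_true(all(chr11$class == "BRANCH"))
  expect_equal(nrow(order_chromosome_events(rep, "21")), 0)
  # the trunk 3q gain survives re-projection
  chr3 <- order_chromosome_events(rep, "3")
  expect_true("TRUNK" %in% chr3$class)
})
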