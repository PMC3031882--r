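hg <- genome_model(n_probes = 50)

two_group_matrix <- function(shared = 2, private = 3) {
  # two groups of two samples; groups differ by 2*private events
  trunk <- make_events(hg, as.character(1:shared),
                       start = 10, end = 40, kind = "GAIN")
  pa <- make_events(hg, as.character(5:(4 + private)),
                    start = 10, end = 40, kind = "LOSS")
  pb <- make_events(hg, as.character(12:(11 + private)),
                    start = 50, end = 80, kind = "LOSS")
  ga <- new_event_table(rbind(as.data.frame(trunk), as.data.frame(pa)))
  gb <- new_event_table(rbind(as.data.frame(trunk), as.data.frame(pb)))
  match_events(list(q1_wk0 = ga, q2_wk0 = ga, q3_wk0 = gb, q4_wk0 = gb))
}
new_event_table <- cghclone:::new_event_table

test_that("identical samples form one subpopulation with every event HOM", {
  ev <- make_events(hg, c("3", "11"), list(153.8, 94.8),
                    list("QTEL", "QTEL"), c("GAIN", "LOSS"))
  m <- match_events(list(q1_wk0 = ev, q2_wk0 = ev, q3_wk0 = ev))
  labels <- assign_subpopulations(m)
  expect_equal(unname(labels), rep("A", 3))
  het <- classify_hom_het(m, labels = labels)
  expect_true(all(het$status == "HOM"))
  v <- case_verdict(labels, m, het)
  expect_false(v$heterogeneous)
  expect_equal(v$n_subpopulations, 1)
})

test_that("well-separated groups are recovered exactly", {
  m <- two_group_matrix(shared = 2, private = 3)
  labels <- assign_subpopulations(m, d_split = 3)
  expect_equal(length(unique(labels)), 2)
  expect_equal(unname(labels[c("q1_wk0", "q2_wk0")]), c("A", "A"))
  expect_equal(unname(labels[c("q3_wk0", "q4_wk0")]), c("B", "B"))
  het <- classify_hom_het(m, labels = labels)
  expect_equal(sum(het$status == "HOM"), 2)
  expect_true(case_verdict(labels, m, het)$heterogeneous)
})

test_that("differences below d_split count as subclonal variation", {
  m <- two_group_matrix(shared = 3, private = 1)  # groups 2 events apart
  labels <- assign_subpopulations(m, d_split = 3)
  expect_equal(length(unique(labels)), 1)
})

test_that("consensus mode tolerates detection dropout, raw mode does not", {
  m <- two_group_matrix(shared = 2, private = 3)
  # drop one shared event from one sample (detection dropout)
  j <- which(colSums(m$presence) == nrow(m$presence))[1]
  m$presence["q1_wk0", j] <- FALSE
  labels <- assign_subpopulations(m, d_split = 3)
  het_raw <- classify_hom_het(m, labels = labels, mode = "raw")
  het_con <- classify_hom_het(m, labels = labels, mode = "consensus")
  key <- event_key(m$events)[j]
  expect_equal(het_raw$status[event_key(new_event_table(
    as.data.frame(het_raw)[, 1:7]))== key], "HET")
  expect_equal(het_con$status[event_key(new_event_table(
    as.data.frame(het_con)[, 1:7])) == key], "HOM")
})

test_that("normal-profile samples are excluded from the hom/het rule", {
  m <- two_group_matrix()
  statuses <- data.frame(sample_id = m$samples$sample_id,
                         abnormal = c(TRUE, TRUE, TRUE, FALSE))
  labels <- assign_subpopulations(m, statuses = statuses)
  expect_false("q4_wk0" %in% names(labels))
  st_none <- data.frame(sample_id = m$samples$sample_id, abnormal = FALSE)
  expect_error(classify_hom_het(m, statuses = st_none), "no tumour profile")
})

test_that("verdict modes differ for subpopulations first seen after week 0", {
  ev_a <- make_events(hg, c("1", "2", "3"), 10, 40, "GAIN")
  ev_b <- make_events(hg, c("1", "8", "9", "10"), 10, 40,
                      c("GAIN", "LOSS", "LOSS", "LOSS"))
  m <- match_events(list(q1_wk0 = ev_a, q2_wk0 = ev_a,
                         q1_wk2 = ev_b, q2_wk2 = ev_b))
  labels <- assign_subpopulations(m)
  expect_equal(length(unique(labels)), 2)
  v_inf <- case_verdict(labels, m, mode = "inferred")
  v_wk0 <- case_verdict(labels, m, mode = "week0")
  expect_true(v_inf$heterogeneous)
  expect_false(v_wk0$heterogeneous)
  expect_equal(v_wk0$n_subpopulations_week0, 1)
})

test_that("published hom/het statuses are reproduced from presence alone", {
  for (cid in c("CE01-02", "CE01-09", "CE01-13")) {
    fx <- fixture_case(cid)
    het_raw <- classify_hom_het(fx$matrix, mode = "raw")
    expect_identical(het_raw$status, fx$status_published,
                     info = paste(cid, "raw"))
    het_con <- classify_hom_het(fx$matrix, mode = "consensus")
    expect_identical(het_con$status, fx$status_published,
                     info = paste(cid, "consensus"))
    expect_gte(sum(het_con$status == "HOM"), 1)  # monoclonal origin
  }
})
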