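# Independent oracles and small builders used across the tests.

# Single-chromosome genome with evenly spaced probes.
toy_genome <- function(n_probes = 100, length_bp = 100e6,
                       centromere_bp = length_bp / 2, chrom = "1") {
  genome_model(n_probes,
               chromosomes = data.frame(chrom = chrom,
                                        length_bp = length_bp,
                                        centromere_bp = centromere_bp,
                                        stringsAsFactors = FALSE))
}

toy_profile <- function(values, genome = toy_genome(length(values)),
                        case_id = "T", quadrant = 1, week = 0,
                        cellularity = NA_real_) {
  stopifnot(length(values) == nrow(genome$probes))
  probe_profile(data.frame(probe_id = genome$probes$probe_id,
                           chrom = genome$probes$chrom,
                           pos_bp = genome$probes$pos_bp,
                           log2_ratio = values,
                           stringsAsFactors = FALSE),
                case_id, quadrant, week, cellularity)
}

# Brute-force exhaustive arc search: direct two-sample pooled t over every
# contiguous arc, plain R. Independent of the package's scan. Returns the
# cutpoint set of the maximising split (complementary prefix/suffix arcs
# define the same split).
brute_first_split <- function(x) {
  n <- length(x)
  best <- -1
  cuts <- integer(0)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k == n) next
      xin <- x[(i + 1):j]
      xout <- x[-((i + 1):j)]
      ss <- sum((xin - mean(xin))^2) + sum((xout - mean(xout))^2)
      sp2 <- ss / (n - 2)
      d <- mean(xin) - mean(xout)
      stat <- if (sp2 <= 1e-12 * (mean(x^2) + 1)) {
        if (abs(d) > 1e-9) Inf else 0
      } else {
        abs(d) / sqrt(sp2 * (1 / k + 1 / (n - k)))
      }
      if (stat > best) {
        best <- stat
        cuts <- setdiff(unique(c(i, j)), c(0L, n))
      }
    }
  }
  list(stat = best, cuts = sort(cuts))
}

arc_cuts <- function(res, n) sort(setdiff(unique(c(res$i, res$j)), c(0L, n)))

# Tiny two-lineage event matrix built from explicit event tables.
matrix_from_lists <- function(lists, tol_mb = 1, case_id = "toy") {
  match_events(lists, case_id = case_id, tol_mb = tol_mb)
}

expect_clade <- function(rooted, tips) {
  m <- ape::getMRCA(rooted, tips)
  clade <- ape::extract.clade(rooted, m)
  expect_setequal(clade$tip.label, tips)
}
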