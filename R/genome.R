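#' Chromosome table for the hg18-era reference frame
#'
#' Chromosome lengths and centromere midpoints (NCBI36/hg18 assembly, the
#' coordinate frame in which the study's event tables are reported, to one
#' decimal Mb). All autosomes plus X; the cohort is all female, so X is
#' carried at a diploid baseline like the autosomes.
#'
#' @return A data.frame with columns `chrom`, `length_bp`, `centromere_bp`.
#' @export
hg18_chromosomes <- function() {
  data.frame(
    chrom = c(as.character(1:22), "X"),
    length_bp = c(
      247249719L, 242951149L, 199501827L, 191273063L, 180857866L,
      170899992L, 158821424L, 146274826L, 140273252L, 135374737L,
      134452384L, 132349534L, 114142980L, 106368585L, 100338915L,
      88827254L, 78774742L, 76117153L, 63811651L, 62435964L,
      46944323L, 49691432L, 154913754L
    ),
    centromere_bp = as.integer(1e5 * c(
      1243, 933, 917, 509, 477, 605, 588, 452, 488, 403, 527, 355,
      179, 172, 184, 368, 232, 171, 268, 277, 132, 147, 606
    )),
    stringsAsFactors = FALSE
  )
}

#' Build a genome model with a synthetic probe grid
#'
#' A genome model couples a chromosome table (lengths, centromeres) with an
#' ordered probe grid, emulating a whole-genome CGH array laid out evenly
#' along each chromosome. Probes are allocated to chromosomes proportionally
#' to length and spaced uniformly, so a 4,000-probe grid has roughly 0.8 Mb
#' spacing; the real platform (~180k probes) can be emulated by raising
#' `n_probes`.
#'
#' @param n_probes Total number of probes across the genome (default 4000).
#' @param chromosomes Chromosome table (`chrom`, `length_bp`, `centromere_bp`);
#'   defaults to [hg18_chromosomes()]. A subset may be supplied for small
#'   test genomes.
#' @return An object of class `genome_model`: list with `chromosomes` and
#'   `probes` (`probe_id`, `chrom`, `pos_bp`, ordered by chromosome then
#'   position).
#' @export
genome_model <- function(n_probes = 4000, chromosomes = NULL) {
  chrs <- if (is.null(chromosomes)) hg18_chromosomes() else chromosomes
  stopifnot(
    is.data.frame(chrs),
    all(c("chrom", "length_bp", "centromere_bp") %in% names(chrs)),
    nrow(chrs) >= 1, n_probes >= nrow(chrs)
  )
  if (any(chrs$centromere_bp <= 0 | chrs$centromere_bp >= chrs$length_bp)) {
    stop("centromere must lie strictly inside each chromosome")
  }
  total <- sum(as.numeric(chrs$length_bp))
  n_per <- pmax(1L, as.integer(round(n_probes * chrs$length_bp / total)))
  probes <- do.call(rbind, lapply(seq_len(nrow(chrs)), function(i) {
    n <- n_per[i]
    spacing <- chrs$length_bp[i] / n
    pos <- as.integer(round(spacing * (seq_len(n) - 0.5)))
    pos <- sort(unique(pos))
    data.frame(chrom = chrs$chrom[i], pos_bp = pos, stringsAsFactors = FALSE)
  }))
  probes$probe_id <- sprintf("P%05d", seq_len(nrow(probes)))
  probes <- probes[, c("probe_id", "chrom", "pos_bp")]
  gm <- structure(list(chromosomes = chrs, probes = probes),
                  class = "genome_model")
  validate_genome_model(gm)
  gm
}

validate_genome_model <- function(gm) {
  stopifnot(inherits(gm, "genome_model"))
  for (ch in gm$chromosomes$chrom) {
    p <- gm$probes$pos_bp[gm$probes$chrom == ch]
    if (length(p) && any(diff(p) <= 0)) {
      stop("probe positions must be strictly increasing within chromosome ", ch)
    }
  }
  invisible(gm)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosomes, %d probes\n",
              nrow(x$chromosomes), nrow(x$probes)))
  invisible(x)
}

chrom_row <- function(genome, chrom) {
  i <- match(as.character(chrom), genome$chromosomes$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  genome$chromosomes[i, ]
}

#' Resolve a coordinate token to a basepair position
#'
#' The event dialect anchors interval endpoints at arm landmarks: `PTEL`
#' (p-terminus, 0), `CEN` (centromere) and `QTEL` (q-terminus, chromosome
#' end). Numeric endpoints are Mb values.
#'
#' @param genome A `genome_model`.
#' @param chrom Chromosome name.
#' @param x Either a numeric Mb position or one of `"PTEL"`, `"CEN"`, `"QTEL"`.
#' @return Position in bp.
#' @export
resolve_endpoint <- function(genome, chrom, x) {
  row <- chrom_row(genome, chrom)
  if (is.character(x)) {
    switch(toupper(x),
      PTEL = 0,
      CEN  = as.numeric(row$centromere_bp),
      QTEL = as.numeric(row$length_bp),
      {
        v <- suppressWarnings(as.numeric(x))
        if (is.na(v)) stop("bad endpoint token: ", x)
        v * 1e6
      }
    )
  } else {
    as.numeric(x) * 1e6
  }
}

#' Format a basepair position in the reporting dialect (Mb, one decimal)
#' @param bp Position in bp.
#' @return Numeric Mb rounded to one decimal.
#' @export
bp_to_mb <- function(bp) round(bp / 1e6, 1)

probe_positions <- function(genome, chrom) {
  genome$probes$pos_bp[genome$probes$chrom == as.character(chrom)]
}
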