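---
title: "Tracking tumour subpopulations with multi-region array CGH: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking tumour subpopulations with multi-region array CGH: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghclone)
```

# The problem

A solid tumour is rarely one genotype. Cells descend from a single
transformed founder, but genomic instability during growth lets lineages
diverge, so spatially separate regions of one tumour can carry different
sets of copy-number aberrations. When such a tumour is treated, the
subpopulations may respond differently — a minor, intrinsically resistant
clone can survive and repopulate while the dominant clone is cleared —
which is one mechanism behind disease persistence and relapse.

`cghclone` implements the analysis chain needed to study this with
multi-region, multi-timepoint array CGH: four quadrantic core biopsies of a
cervical carcinoma at up to three timepoints (weeks 0, 2 and 5 of
chemoradiotherapy), each profiled as probe-level log2 ratios of tumour
versus diploid reference DNA. The chain is

1. **Preprocessing** — median normalisation, then circular binary
   segmentation (CBS) into piecewise-constant segments;
2. **Calling** — copy-number state per segment
   (`HOMDEL < LOSS < NEUTRAL < GAIN < AMP`) and a per-profile
   abnormal/normal flag;
3. **Events** — segments become named aberration events in a
   telomere/centromere dialect (`"153.8-q tel Gain"`), matched across a
   case's samples into a unified catalogue with a presence matrix;
4. **Heterogeneity** — homogeneous (in every subpopulation) versus
   heterogeneous events; samples clustered into subpopulations; a
   per-case verdict;
5. **Phylogeny** — a neighbour-joining tree over sample genotypes plus an
   artificial diploid normal, and trunk (early) event inference;
6. **Dynamics** — a quadrant-by-week subpopulation map and per-quadrant
   clearance / persistence / replacement calls.

A ground-truthed clone-mixture simulator makes every stage testable
without any external download, and machine-readable transcriptions of the
study's clinical table and rearrangement table are packaged so the
event-level analysis can be reproduced exactly from printed data.

# Models and procedures

## Mixture model for probe signal

A biopsy contains a fraction $c$ (cellularity) of tumour cells and $1-c$
diploid stroma. If clone $i$ has integer copy number $n_i$ at a probe and
holds fraction $f_i$ of the tumour compartment, the expected log2 ratio is

$$\log_2\!\frac{c\sum_i f_i\,n_i + (1-c)\cdot 2}{2},$$

floored at $-4$ to avoid infinities under homozygous deletion. Stromal
dilution shrinks every aberration toward 0: a single-copy gain reads
$\log_2 1.5 \approx 0.585$ in pure tumour but $\approx 0.07$ at 10%
cellularity — below any sensible calling threshold, which is why
low-cellularity biopsies legitimately read "normal". The same equation is
inverted (given $c$, default 1 when unknown) to estimate integer copy
levels when converting segments to events.

## Circular binary segmentation

Each chromosome's probe sequence is treated as a circle. For every arc the
pooled-variance two-sample $t$ statistic compares probes inside versus
outside; the maximising arc is a candidate split, accepted when its
permutation p-value (fraction of label permutations whose own maximal arc
statistic reaches the observed one) is below `alpha` (default 0.01,
default 10,000 permutations; the tests use 300–1,000). Accepted splits
recurse until nothing is significant; adjacent segments closer than
`undo_sd` (default 1) residual MADs are then re-merged.

Numerical choices worth knowing:

* For fixed arc width $k$ the statistic is monotone in the squared mean
  contrast (within-arc sum of squares decomposes as
  $SS_w = TSS - \tfrac{k(n-k)}{n}d^2$), so only the arcs with extreme
  window sums per width need evaluation — an $O(n)$ sweep per width.
* Zero pooled variance with distinct means scores $+\infty$ (noiseless
  data split exactly); with equal means it scores 0.
* Ties break by smallest start index, then smallest width. A prefix arc
  and its complementary suffix arc define the same split and tie exactly.
* Permutation streams are per-chromosome Mersenne Twister generators
  seeded from the global seed, so results are reproducible and
  independent of R's RNG state. Scanning stops as soon as the
  accept/reject decision is forced, which never changes the decision.
* Chromosomes with fewer than 4 probes are returned as single segments.

The permutation test has an intrinsic resolution limit: a pure block of
$k$ probes inside $n$ has exact p-value about $(n-k+1)/\binom{n}{k}$, so
1–2 probe features sit near or above `alpha` and are (correctly) not
split. The event-level probe floor (`event_min_probes`, default 5) and
the simulator's placement geometry (below) respect this.

## Event dialect, matching and tolerance

Maximal runs of same-direction non-neutral segments become one event;
focal structure nests: a within-run region at two or more extra copies is
an additional `FURTHER_GAIN`, amplification-grade segments
(mean > 1.5) emit `AMP`, homozygous-deletion-grade (mean < −1.5)
emit `HOMDEL`. Endpoints within `snap_tol_mb` of the p-terminus,
centromere or q-terminus are re-anchored to `PTEL`/`CEN`/`QTEL`
(`PTEL–QTEL` prints as "Whole chr"); coordinates are reported in Mb to
one decimal.

Two events match iff same chromosome, kind and copy level, landmark
anchors agree token-for-token, and numeric endpoints agree within
`tol_mb`. The defaults (1 Mb for both tolerances) suit the printed
tables' one-decimal resolution. On a synthetic grid the right scale is a
few probe spacings: the noisy benchmark (4,000 probes, ~0.8 Mb pitch)
uses 3 Mb for both. An event matching several catalogue entries joins the
nearest by summed endpoint distance, ties to the earlier entry.

## Subpopulations, hom/het and the verdict

Aberrant samples are clustered by average linkage on the event Hamming
distance and the dendrogram is cut at the largest merge-height gap, with
merges below `d_split` (default 3 events) never separating clusters:
fewer than `d_split` differing events is treated as subclonal variation
within one population, not a distinct subpopulation. The threshold is an
explicit operationalisation — no numeric rule for this boundary exists in
the source tables — and it is the main tunable of the heterogeneity
stage.

Each subpopulation's *consensus genotype* holds the events present in at
least half of its samples, which tolerates detection dropout in
low-cellularity biopsies. An event is homogeneous (`HOM`) when every
consensus carries it (default "consensus" mode; "raw" mode requires
presence in every aberrant sample). Normal-profile samples never
participate — their flat profiles reflect stroma, not genotype. A case is
heterogeneous when it has at least two subpopulations; the default
"inferred" verdict counts every subpopulation ever observed, because a
clone first detected mid-treatment in several quadrants at once is far
more plausibly a pre-existing population unmasked by clearance of the
dominant clone than a sweep arising within two weeks ("week0" mode counts
only week-0 labels).

## Phylogeny and early events

Leaves are the aberrant samples plus an all-zero diploid `NORMAL`
genotype; distances are event Hamming distances; the tree is
neighbour-joining, so branch lengths are in event units and, on additive
inputs (perfect phylogeny, complete detection), leaf-to-leaf path lengths
equal the input distances exactly. NJ was preferred over parsimony
because branch lengths proportional to evolutionary distance are wanted
directly. Negative NJ branches are clamped to zero with the deficit moved
to the sibling branch. Trees are displayed rooted at `NORMAL`.

Subpopulations share only events that predate their divergence, so the
trunk is the intersection of the subpopulation consensus genotypes;
everything else is a branch event. `order_chromosome_events()` re-projects
this onto one chromosome as a pre-/post-divergence narrative.

## Treatment dynamics

The subpopulation map assigns each (quadrant, week) cell a label,
`NORMAL` (sample exists, profile not abnormal) or `MISSING` (no sample).
Trajectories compare the first observed state with the week-5 state:
`CLEARANCE`, `PERSISTENCE`, `REPLACEMENT`, `NO_TUMOUR`, `EMERGENCE`. A
quadrant with no week-5 sample gets no call — missing cores are not
imputed. Week-2 samples inform the map and the clustering but not the
trajectory classes, which are defined on the week 0 → 5 endpoints.

# The simulator: what it emulates, and what it does not

`sim_config()` defines the study conditions: `n_trunk` founder events
(default 4), `n_lineages` diverging lineages (default 2) with `n_branch`
private events each (default 6), placed uniformly over chromosome arms
with log-uniform lengths between `min_event_mb` and the arm length, a
small probability (0.05) of whole-chromosome events, and a 0.1
probability that a gain carries a nested further gain. Lineages occupy
quadrants round-robin; per-biopsy cellularity is uniform on
`cellularity_range` (default 0.4–0.9, the range over which single-copy
events remain callable at the default thresholds); probe noise is i.i.d.
Gaussian, default sd 0.15 log2 units. Treatment multiplies each lineage's
fraction by a per-clone survival (default one sensitive, one resistant:
0.01 and 0.5), exposure-scaled for intermediate weeks; tumour content
shrinks accordingly and clones whose fraction of total cells falls below
`detect_floor` (default 0.10, consistent with reported minor-clone
detection limits around 13%) become undetectable in truth.

Placement enforces identifiability at the chosen probe resolution: events
snap to probe positions, keep `buffer_probes` neutral probes between
events and to any chromosome end they do not reach, and partial events
may cover at most half of a chromosome's probes. These are generator
design choices matched to the permutation test's resolution limit
described above — without a neutral majority and multi-probe gaps, exact
segment recovery is not a well-posed target even with zero noise.

The simulator deliberately omits dye bias, GC waves, probe-specific
variance, SNP-array allele fractions, subclonal point mutations and
event loss/homoplasy (genotypes are a perfect phylogeny by construction).
Passing the synthetic benchmarks therefore demonstrates correctness of
the analysis chain under the stated noise model, not robustness to
platform artefacts — on real arrays, artefact correction upstream of this
pipeline would be essential.

# Benchmarks and problem sizes

Two seeded suites (also run by `scripts/acceptance.R`) fix the evaluation
conditions; sizes were chosen to exercise the full chain at depth while
keeping a complete run at desk scale:

* **Noiseless** (50 runs): cellularity 1, sd 0, events ≥ 10 probes on a
  2,000-probe grid, weeks 0 and 5. Required outcome: exact recovery of
  the event catalogue, trunk set, partition and trajectory classes in
  every run.
* **Noisy** (100 runs): sd 0.15, cellularity 0.4–0.9, single-copy
  gains/losses ≥ 20 probes on a 4,000-probe grid, week 0; matching and
  snapping at 3 Mb. Reported outcome: trunk-event recovery and exact
  partition match rates (accepted at ≥ 90%; both measure 99–100% in
  practice).
* **Additivity** (50 runs): NJ path lengths equal event distances within
  1e-9 on perfect-phylogeny matrices.

# Known limitations

* The sample clustering is hard: a biopsy that physically contains a
  mixture of two clones (so its event set straddles two lineages) can
  come out as its own singleton cluster rather than being assigned to a
  lineage. The packaged rearrangement table contains exactly this
  situation (one quadrant sharing one lineage's focal ladder and the
  other lineage's defining arm events); trunk inference is robust to it
  (intersection over consensuses), but the map then shows a third label.
  A fractional-membership (mixture) model is the principled fix and is
  out of scope here.
* "Further gain" in the reporting dialect is treated as a distinct,
  level-2 event matched only against further gains. In the printed
  tables such rows are sometimes adjacent to (rather than nested in)
  their companion gain; the matcher handles both because matching is
  per-row, but the simulator only generates the nested form.
* The hom/het rule and the trunk rule can disagree about an event that is
  present in every consensus but absent from one raw sample — this is by
  design (consensus mode), and the "raw" mode is available where strict
  per-sample presence is wanted.
* Trajectory calls condition on the bookkeeping table's sample
  availability; a quadrant whose week-5 core is missing gets no call even
  if other evidence (e.g. histopathology) exists.
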