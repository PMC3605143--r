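---
title: "Detecting structural variation from discordant read pairs in linear time"
author: "svstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structural variation from discordant read pairs in linear time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svstream)
library(data.table)
```

## The problem and the model

A DNA fragment sequenced from both ends yields a mate pair whose two reads,
once mapped to a reference, should sit close together (the insert size), on
the same chromosome, in FR-inward orientation (leftmost read forward,
rightmost reverse). A genomic rearrangement in the sample disturbs this
geometry for every fragment spanning a breakpoint: a deletion stretches the
apparent insert, an inversion flips one read's strand, a translocation puts
the two reads on different chromosomes. Calling structural variation (SV)
from such discordant ("odd") pairs is classically done by pairwise
comparison of reads, which scales nonlinearly and becomes prohibitive on
cohorts of high-coverage genomes.

`svstream` takes the rule-based, streaming alternative. Each pair is
classified once, by precedence:

1. `INTERCHROM` — ends on different chromosomes (no single-axis distance
   exists, so this outranks everything);
2. `ORIENTATION` — strands inconsistent with FR-inward geometry, regardless
   of distance;
3. by distance `d = posB − posA`: `WINDOW_DISTANCE` for
   `window_min < d ≤ window_max`, `BEYOND_WINDOW` for `d > window_max`,
   otherwise `NORMAL`.

Classified pairs are accumulated into coarse spatial bins: a 1D structure
holding per-bin pair coverage and per-class discordant counts, and a 2D
structure keyed by the canonically ordered (bin of end A, bin of end B) cell
holding one record per distinct supporting pair. A second linear pass merges
adjacent 2D cells of the same class into candidate features, computes each
candidate's support and local coverage, filters, and scores.

The score of a feature with supporting mapping qualities `q_1..q_k` is

    score = 1 − ∏ 10^(−q_i / 10)

— the probability that not all supporting pairs were mismapped, under the
Phred interpretation `P(mismap) = 10^(−q/10)`. It increases with both the
number of supports and their qualities; a feature supported solely by mapq-0
reads scores exactly 0. Mathematically the score is strictly monotone in
every argument; in double precision it saturates at 1 once `Σ q_i` exceeds
about 160, which the tests account for.

## Parameters and their defaults

| parameter | default | units | why |
|---|---|---|---|
| `bin_size` | 1000 | bases | the longest distance still regarded as a normal insert; in a clean germline library only ~0.1% of pairs map farther apart, so nearly every normal pair falls inside one bin |
| `window_min`, `window_max` | 1000, 7000 | bases | the discordant-distance window. Pair distances in (1000, 7000] are enriched in tumor over matched germline samples; distances beyond 7000 are not and are tallied as `BEYOND_WINDOW` but excluded from calling (`count_beyond_window` re-admits them) |
| `min_support` | 3 | pairs | a cluster must have more than two distinct supporting pairs; `--min-support 2` gives the permissive variant, and both behaviors are tested |
| `min_support_fraction` | 0.05 | — | supports must exceed 5% of local coverage, suppressing mismapping noise in deep regions |
| `adjacency_radius` | 1 | bins | 2D cells within one bin on both axes merge by single linkage, resolving clusters straddling bin boundaries |
| `default_mapq_for_unavailable` | 20 | Phred | substituted for mapq 255 ("unavailable") in scoring only, never in classification |

Boundary conventions: bins are half-open `[k·1000, (k+1)·1000)`; the
distance window is `(window_min, window_max]`, so `d = 1000` is normal
("more than 1000 bp" is the abnormal tail) and `d = 7000` is in-window.
Internally all coordinates are 0-based half-open; SAM's 1-based positions
are converted at the I/O boundary. Chromosome order is the order of the
input file's sequence dictionary, which fixes the canonical 2D keys without
imposing a naming scheme.

Local coverage of a candidate is the number of pairs of *any* class whose
leftmost end falls in the candidate's bins on either axis, deduplicated per
pair. The accumulator therefore carries two coverage tallies: `COVERAGE`
(a pair counted at both ends' bins, once per bin) for coverage tracks, and
`COVERAGE_LEFT` (once per pair, at the leftmost end's bin) whose sums over
disjoint bins are exactly deduplicated pair counts. Classes are never mixed
within one call: a region supported by both orientation and distance
evidence produces two calls.

## Linearity and the merge contract

Both passes touch each pair or cell a constant number of times, so runtime
is linear in stream size. More importantly the accumulator is a commutative
monoid: `merge()` of partial accumulators from any partition of a stream is
*bit-exact* equal to single-pass accumulation, with the empty accumulator as
identity. That is what makes the analysis distributable map-reduce style —
partitions can be processed on separate workers and reduced — while staying
exactly reproducible. The test suite asserts bit-exactness of both the
merged accumulators and the final BEDPE output over random streams and
partitions; accumulators also serialize to a sorted, line-oriented TSV dump
that round-trips bit-exact, so an external reducer can merge partial results
from separate processes.

Binned clustering trades resolution for this linearity: two odd pairs less
than `bin_size` apart always land in the same or adjacent bins, so
single-linkage clusters whose coordinate span is below one bin are recovered
exactly (the suite checks equivalence with a brute-force single-linkage
oracle at linkage distance = bin size). The converse is not guaranteed:
distinct tight clusters separated by only one or two bins can merge under
binned adjacency although exact single linkage keeps them apart. The
equivalence tests therefore place generated clusters at least three bins
apart, which is the regime where binned and exact clustering coincide;
closer event pairs are reported merged, at bin resolution, by design.

## Quality assurance

*Insert-size distribution.* `estimate_insert_distribution()` builds a
Gaussian-kernel density (Silverman's bandwidth) of intrachromosomal pair
distances with empirical quantiles and tail fractions. `tail_fraction(d,
1000)` directly measures the clean-library regime (~0.1% of pairs beyond
1000 bp); a tumor sample shows the (1000, 7000] enrichment instead.

*Read groups.* Library or run batches are compared with the pooled sample
by the two-sample Kolmogorov–Smirnov statistic on insert distances and by
the ratio of discordant-pair rates. A single anomalous group contaminates
the pool it is compared against — with `g` groups a clean group's KS
statistic is bounded below by about `1/g` — so flagging is iterative: the
worst offender over the thresholds (KS > 0.1 or rate ratio > 2) is removed
from the pool and the rest re-tested until stable. Reported statistics are
against the final clean pool: a group with inserts shifted by +5000 bases
shows KS ≈ 1 while clean groups show only sampling noise. Groups under 500
pairs are exempt ("insufficient") rather than unstably flagged. The KS
statistic and both thresholds are this package's choices — distribution-free,
matching the nonparametric treatment of insert sizes — and are configurable.
Note the identifiability limit: with two equal-sized groups a pooled
comparison cannot tell which one is anomalous.

*Usable regions.* `select_usable_regions()` keeps maximal runs of
consecutive bins with ≥ `min_cov` pairs (default 8) in ≥
`min_fraction_samples` of samples (default 0.9), so cross-sample comparison
is restricted to comparably covered territory. Both defaults are declared
package choices exposed as configuration; raising `min_cov` never enlarges a
region (tested). A matched tumor/blood pair passes QA only if both samples
pass.

## Cross-sample comparison

Per-sample calls are aggregated over a BED gene annotation into a genes ×
samples disruption matrix (a call increments every gene its two regions
overlap). Sample profiles are compared with the normalized
mutual-information distance

    D(x, y) = 1 − I(X; Y) / H(X, Y)

with plug-in entropies from the joint histogram (0·log 0 = 0, no
small-sample correction; the entropy ratio is base-free). On discrete
profiles this form is a metric — `D(x, x) = 0`, symmetric, `D = 1` under
independence, triangle inequality — which the suite verifies to 10⁻⁹ on
random binary triples along with an exhaustive-oracle agreement to 10⁻¹².
Profiles are binarized (disrupted / not) by default because presence of
disruption, not its count, is the comparable signal across unevenly covered
samples; 4-bin count-quantile discretization is available. When both
profiles are constant the joint entropy is 0 and D is defined as 0.

The distance matrix feeds classical (Torgerson) multidimensional scaling —
double-center `−D²/2`, take the top eigenpair, coordinate = eigenvector ×
√eigenvalue, sign fixed so the largest-magnitude entry is positive; a
non-positive top eigenvalue raises a degenerate-geometry error rather than
returning an arbitrary axis. Group separation along the first coordinate is
summarized by per-label kernel densities and by a cluster compactness index:
with `S` the sum of within-cluster distances over its `m` pairs and
`S_min`/`S_max` the sums of the `m` smallest/largest distances overall, the
index is `1 − (S − S_min)/(S_max − S_min)` — the complement of the
Hubert–Levin C statistic, oriented so 1 is maximally compact, matching the
convention that a good cluster scores high. The Pearson correlation between
per-gene coverage and per-gene disruptions is reported as a batch-effect
diagnostic (near 0 is the desired outcome; zero-variance inputs are flagged
undefined rather than raising).

*Coverage-consistency biclustering.* To find genes × samples with
comparable coverage, `bicluster_consistent()` uses greedy node deletion with
the mean squared residue criterion (variance around the additive
row + column + grand means fit): the row or column with the largest mean
residue is removed until the matrix residue falls below `max_variance`, then
a node-addition phase re-admits, in index order, any deleted row or column
whose residue against the found bicluster is no worse than the achieved
residue. The addition phase matters: deletion alone follows a greedy path
that can strand members of the consistent block (and the superficially
attractive alternative — deleting whichever node most reduces the overall
residue — is worse, collapsing into degenerate two-row strips because a
near-empty matrix is trivially fittable). With deletion + addition, a
planted 10 × 10 consistent-coverage block in a 30 × 30 erratic matrix is
recovered in 20/20 seeded replicates. Note that "consistent" means *low
residual variance*: a block at an elevated mean but high scatter is not a
target, and no variance-criterion deletion would retain one.

## The simulator

`sim_config()` defines the study conditions under which every stage is
testable without external data: a multi-chromosome reference (default two
5-Mb chromosomes), pairs with leftmost positions uniform over chromosomes,
FR-inward orientation, insert sizes N(400, 50²) truncated positive (so the
normal tail beyond 1000 bp is essentially zero and the ~0.1% discordant rate
comes entirely from the mismapping-noise fraction, default 0.001, which
reassigns a pair's mate to a uniformly random chromosome, position and
strand at mapq 15 versus 60 for true mappings), and a background density of
10 pairs/kb — roughly ten pairs per bin, a desk-scale stand-in for
exome-like depth. Planted events emit configurable numbers of supporting
pairs: deletions add their size (default 3000, inside the enriched window)
to an insert draw; inversions emit same-strand pairs; translocations emit
inter-chromosomal pairs; all positions jittered within one bin of the
breakpoint. One seeded generator per scenario with a fixed draw order
(positions, inserts, noise mask, noise coordinates, then each event's
jitters) makes streams byte-identical across runs; `write_sam()` emits
coordinate-sorted, well-formed SAM (placeholder sequence — mapping itself is
not modeled, only its output) that `read_pairs()` reconstructs exactly.

What the simulator does *not* emulate bounds what green tests prove:
no base-level errors or aligner behavior, no chimeric/split reads, no
coverage waviness (GC bias), no copy-number structure, no breakpoint
micro-homology. Sensitivity and specificity measured here are properties of
the geometric rule system under idealized mapping, not of any aligner
pipeline. Problem sizes used in the checked properties are a 10-Mb genome,
noise 0.001, and 100 seeded matched-pair replicates, with events supported
by 6–10 pairs; under those conditions recovery of all planted events and ≤ 1
false blood call per sample is the measured outcome.

## Numerical and degenerate-input choices

- `bin_index` rejects negative positions and non-positive bin sizes;
  unknown chromosomes are skipped with a warning and a tally, preserving the
  conservation identity (pairs in = coverage tallies + skips).
- Read-name sets deduplicate pairs observed twice; mate pairing in
  `read_pairs()` is by template name with the mate-reference fields as a
  consistency check, and every skipped record is tallied by reason.
- Deterministic ordering everywhere: candidates sort by regionA then
  regionB then class; BEDPE rows sort by (chrom1, start1, chrom2, start2)
  with scores at fixed 4-decimal rounding; ties in biclustering prefer rows,
  then the earlier index. Detection itself uses no randomness.
- `c_index` returns 1 with a warning when all pairwise distances are equal
  (the bound `S_max − S_min` vanishes).
- Distances entering the insert-size density are capped at `max_d`
  (default 10⁶) to keep the grid bounded; quantiles and tail fractions use
  the uncapped sample.

## A worked example

```{r example}
cfg <- sim_config(
  seed = 42, chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
  planted = list(
    planted_sv("deletion", "chr1", 5e5, size = 3000, n_support = 8),
    planted_sv("inversion", "chr1", 1.2e6, n_support = 8),
    planted_sv("translocation", "chr1", 8e5,
               partner_chrom = "chr2", partner_pos = 6e5, n_support = 8)))
sc <- scenario_matched_pair(cfg, dir = tempfile())

tumor <- read_pairs(file.path(sc$dir, "tumor.sam"), sample_id = "tumor")
acc <- pass1(tumor)
calls <- call_svs(acc, sample_id = "tumor")
calls[, c("chromA", "startA", "chromB", "startB", "sv_class",
          "n_support", "support_fraction", "score")]
match_calls_to_truth(calls, sc$truth, names(cfg$chrom_lengths))

blood <- read_pairs(file.path(sc$dir, "blood.sam"), sample_id = "blood")
nrow(call_svs(pass1(blood), sample_id = "blood"))
tail_fraction(estimate_insert_distribution(blood), 1000)
```

## Known limitations

- Resolution is one bin (1000 bp); there is no base-pair breakpoint
  refinement and no event reconstruction beyond the class label.
- Events whose breakpoints lie within 1–2 bins of another event of the same
  class merge into a single call.
- The FR-inward orientation model covers standard paired-end chemistry;
  everted/overlapping short-insert artifacts fall under `ORIENTATION` or
  `NORMAL` rather than a dedicated class.
- The read-group QA cannot identify the anomalous member of exactly two
  equal groups, and the pooled-KS thresholds assume several read groups of
  ≥ 500 pairs.
- All empirical performance statements above are under the simulator's
  idealized conditions; real libraries add mapping artifacts the rule
  system does not see.
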