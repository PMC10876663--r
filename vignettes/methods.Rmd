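---
title: "Methods: TF prioritization from hypomethylated regulatory regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF prioritization from hypomethylated regulatory regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hypoTF` implements a desk-scale reconstruction of the epigenomic
TF-prioritization strategy used in enhancer-hypomethylation studies of
solid tumors: tumor-specific hypomethylated regions (hypoDMRs) are treated
as candidate regulatory elements, TF binding is inferred from sequence
motifs, open chromatin restricts element–gene linking, and preranked GSEA
of the inferred targets in a tumor-versus-normal expression ranking scores
each TF's regulatory output. This vignette documents the models, the
tunable parameters, the synthetic benchmark, and the design decisions that
were genuinely open.

## Coordinate and data conventions

All intervals are BED-style 0-based half-open `[start, end)`; overlap of
two intervals is `min(end) - max(start)` bp, so abutting intervals do not
overlap. Gene annotations are accepted as BED6 with the gene id in the
name column; the TSS is `start` for `+` genes and `end - 1` for `-` genes.
Nearest-gene assignment measures from the region midpoint
`floor((start + end)/2)` to the TSS — the convention of distal-element
linking, where the element center, not its edge, is the anchor — and
breaks exact ties by the lexicographically smaller gene id (C locale) so
results are machine-independent. No maximum linking distance is imposed by
default (`max_link_distance = Inf`); peak-to-gene assignment for
signatures, by contrast, defaults to a 25 kb cap (below).

## hypoDMR calling

Input is a region × sample matrix of beta values in [0, 1] with
tumor/normal labels. Per region we use a Welch two-sample *t*-test on raw
betas, BH-adjusted across tested regions; a hypoDMR requires
Δβ ≤ −`delta_min` (default 0.2, common WGBS practice) and q ≤ `q_max`
(default 0.05). M-value transforms and CpG-level smoothing are
deliberately out of scope; the test is documented as swappable. Regions
with fewer than two usable samples in either group are flagged `untested`
and never called. Degenerate rows (zero variance in both groups) get
p = 1 when group means agree and p = 0 when the groups are perfectly
separated — the limiting behavior of the *t*-statistic, and required so a
fully separated region is callable.

## Motif scanning and enrichment

PWMs are per-position base probabilities (pseudocount 1e-4, columns
renormalized), scored as log₂ odds against the background (uniform by
default). Both strands are scanned — the minus strand as the
reverse-complemented matrix against the forward sequence — and windows
containing `N` are skipped. A hit requires score ≥ `threshold_frac` ×
the maximum attainable score (default 0.8, standard PWM practice).

Enrichment per TF uses region-level presence/absence in a 2×2 table
(hypoDMRs vs the tested non-hypo background) with a one-sided Fisher
exact test computed as the hypergeometric upper tail, and a
Haldane–Anscombe 0.5 correction on the sample odds ratio when any cell is
zero. Presence/absence was chosen over hit counts because it is robust to
motif self-overlap and exactly testable; the background defaults to all
tested non-DMR regions (matched genomic context) and is configurable.
Note that exact Fisher tests are conservative under the null — on sparse
tables the rejection fraction at 0.05 sits well below 0.05 — which the
test suite asserts in the one direction that is guaranteed
(never anti-conservative).

Candidate TFs are kept at enrichment q ≤ 0.05 with mean tumor expression
above 5, truncated to the top 30 after ordering by q then odds ratio —
the conventional screen thresholds for this analysis.

## Target inference

A hypoDMR qualifies for a TF iff it has ≥ 1 motif hit for that TF **and**
overlaps ≥ 1 ATAC peak by ≥ `min_overlap_bp` (default 1 bp — the minimal
reading of "with open chromatin accessibility"). Each qualifying hypoDMR
contributes its nearest gene; the target set is the deduplicated union,
with full provenance (region, hit count, peak count, distance) retained.
The filter is conjunctive, so an empty ATAC set yields an empty target
set with a warning rather than an error. Promoter exclusion is available
in spirit via `max_link_distance` but no promoter filter is applied by
default, since the underlying analysis does not state one.

## Preranked GSEA

The ranking metric is the tumor/normal log₂ fold change of linear means
with pseudocount 1 (`log2((m_t + 1)/(m_n + 1))`), a deliberately simple
stand-in for count-model differential expression; significance per gene
is a Welch test on log₂(expr + 1). Ties in the ranking are broken by gene
id so the order is deterministic.

The enrichment score walks the ranked list of N genes: at a set member,
+|s|ᵖ / Σ_hits |s|ᵖ (weight exponent p = 1, GSEA "weighted"); at a miss,
−1/(N − k). ES is the signed maximum absolute deviation (earliest
extremum on ties); the running sum ends at 0 within 1e-9 for every p,
which the tests assert. If all hit scores are zero with p > 0 the walk
falls back to p = 0 so the score stays defined.

The null is gene-set permutation — `n_perm` (default 1000) uniform draws
of k genes without replacement — because that is what preranked mode
does; phenotype permutation is out of scope. NES divides ES by the mean
|null ES| of matching sign; the nominal p is
`(1 + #{same-sign nulls ≥ |ES|}) / (1 + #{same-sign nulls})`; the FDR is
the sign-stratified ratio-of-tails estimator over null NES pooled across
the set collection, clipped to [0, 1]. A set with no same-sign null is
reported as undefined with a flag, never silently zero. The permutation
stream is seeded, so results are bit-reproducible. Null ES values are
computed in O(k) per permutation from sorted hit positions (the extremes
of the walk occur adjacent to hits), which keeps 500-simulation
calibration runs and 1000-permutation screens inside seconds.

## TF ranking

The report row per candidate combines enrichment statistics, target-set
size, target NES and FDR, and the TF's own fold change. Eligibility —
GSEA FDR ≤ 0.25 (GSEA's conventional exploratory threshold) and positive
TF fold change — gates the combined rank, which orders by NES then fold
change. The published analysis presents a scatter and picks factors by
eye; the gate-and-sort rule is this package's own formalization and is
fully config-exposed, with the complete table always emitted for
re-ranking.

## Signatures and the stratified screen

Consensus ChIP peaks are the strictest reading of "shared" peaks: each
replicate set is merged, then a consensus interval is a maximal region
simultaneously covered by every set (n-way intersection), which is
deterministic and order-invariant. Peaks map to occupied genes by nearest
TSS within `max_assign_distance` (default 25 kb); the assignment rule for
occupied genes is not stated in the source analyses, so it is explicit
configuration. The signature is occupied ∩ knockdown-downregulated
(log2fc < −`sig_fc_min`, default any decrease, at q ≤ 0.05). Samples are
scored by the mean across signature genes of the per-gene z-score of
log₂(expr + 1) across samples; zero-variance genes contribute z = 0, and
scores are invariant to per-gene affine maps on the log scale.

The stratified screen ranks samples by one stratifier gene, takes the top
and bottom `floor(fraction · n)` (default fraction 0.30; ties broken by
sample id), computes high-vs-low differential expression and runs
preranked GSEA over a pathway collection. Programs anticorrelated with
the stratifier surface with NES < 0.

## The synthetic benchmark

`sim_config()` defaults define the study conditions: 2 chromosomes of
1 Mb, 2000 genes, 500 regions of 200 bp, 20 planted hypoDMRs, 10 tumor vs
10 normal samples, beta noise sd 0.05 with a planted drop of 0.4, 20 TF
motifs of length 8 (1 active, 19 decoys), motif and ATAC coverage of 90%
of true hypoDMRs, regulon up-shift +1 log₂, a 30-gene immune-like program
with anticorrelation coefficient 1, patient expression noise sd 0.5
(log₂), and a knockdown contrast with 6 replicates per arm, −1.5 log₂
knockdown shift and 0.2 replicate noise (cell-line replicates are far
tighter than patient cohorts). Problem sizes were chosen so that the full
20-seed end-to-end recovery studies run in minutes on one core while
leaving the planted effects at realistic magnitudes.

Plantings are constructive: beta means of true hypoDMRs drop by exactly
`hypo_delta` before truncation to [0, 1] (baselines are kept interior so
truncation is negligible); the active TF's consensus is embedded at a
uniform random offset on a random strand, with background motif
occurrences arising only from i.i.d. nucleotide draws; the motif-bearing
and ATAC-overlapping subsets are nested draws from one shuffled order, so
the qualifying set — whose nearest genes define the planted regulon — has
deterministic size min(0.9, 0.9) × 20 = 18, capped at `regulon_size`.
The active TF's tumor expression carries a per-sample activity term
(sd 0.75 log₂) on top of its mean up-shift, and immune-program genes are
shifted by −(activity) per tumor sample, creating the anticorrelation the
screen must recover. Expression is log-normal around per-gene baselines —
fold-change ranking is supported without modeling counts.

What the generator does **not** emulate: CpG-level spatial correlation,
count noise and library-size effects, motif clustering and co-binding,
copy-number structure (amplification exists only as a label), and batch
effects. Passing the planted-truth tests therefore demonstrates that the
pipeline's logic and statistics are correct under the stated noise model,
not that the thresholds are optimal for any particular real cohort.

## Numerical choices and degenerate inputs

Sorting everywhere uses radix (C-locale) order for determinism across
platforms. BH q-values come from `stats::p.adjust`. The Fisher p is the
closed-form hypergeometric tail (identical to `fisher.test`,
alternative = "greater", verified exhaustively for all tables with
margins ≤ 30). Empty candidate lists, empty target sets, empty signatures
and null datasets degrade to empty-but-well-formed outputs rather than
errors; truly contract-violating inputs (betas outside [0, 1], negative
expression, overlapping hypo/background sets, infeasible simulation
geometry) error early with named causes.

## Known limitations

The differential-expression statistic is a Welch test on logs, not a
count model; with few samples per group it is underpowered relative to
shrinkage estimators. The hypoDMR caller is region-level only. Motif
enrichment ignores hit multiplicity and motif similarity, so correlated
PWMs will co-enrich. The FDR estimator for very small set collections is
coarse (pooled nulls dominate). None of these affect the planted-truth
recovery at the default conditions, but all are the places a user should
look first when adapting the pipeline to real cohorts.
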