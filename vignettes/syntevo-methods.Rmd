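---
title: "Methods: synteny, Ks distributions, and ancestral karyotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny, Ks distributions, and ancestral karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`syntevo` infers polyploidy history and karyotype evolution from gene order
and coding sequence: collinear block detection in gene-rank space, syntenic
depth ratios, NG86 Ka/Ks estimation, mixture-model peak detection on Ks
distributions, evolutionary-rate correction against a shared polyploidy
event, molecular dating, collinear gene-retention profiling, and ancestral
chromosome (CAR) reconstruction. A genome-evolution simulator with known
truth backs every stage with parameter-recovery tests. Homolog detection
itself (BLAST/DIAMOND-style searches) is out of scope: homologous gene
pairs are an input.

# Gene order and anchors

All synteny work happens in *rank space*: each gene gets a dense 0-based
rank along its chromosome, ordered by (start, end, gene_id) — the tie-break
makes ranks deterministic for overlapping gene models. Rank space matches
the resolution of gene-order dot plots and removes assembly-scale effects
(intergenic distances, scaffold gaps) from the analysis. Coordinates are
0-based half-open internally; GFF3's 1-based inclusive convention is
converted at the boundary so only one convention exists in memory.

A homolog pair becomes an *anchor* `(chr_a, rank_a, chr_b, rank_b)` with a
strand-agreement flag. Pairs whose ids do not resolve are reported, not
fatal.

# Collinear block chaining

Within each chromosome pair and orientation ("+": `rank_b` ascending;
"`-`": descending), blocks are maximal-scoring chains under

```
score = sum(anchor_score) - gap_penalty * sum((delta_a - 1) + (delta_b - 1))
```

with both rank gaps between consecutive anchors bounded by `max_gap`
(default 25). The chain search is an exact O(n^2) dynamic program;
non-overlapping blocks are extracted greedily (best chain over both
orientations, remove its anchors, repeat), so an anchor joins at most one
block. Chains shorter than `min_block_size` (default 5) are discarded.
Ties break by (score, anchor count, chromosome names), making output
bit-reproducible.

Defaults: `anchor_score = 1` when the input has no scores and
`gap_penalty = 0.05` per rank of gap. The penalty ratio matters: after
heavy post-polyploid gene loss roughly every other ancestral gene is
missing from a duplicated copy, so the expected gap cost per extension step
is about one rank. A penalty near 1 per rank would make extension
score-neutral — a random walk whose maxima fragment blocks — while the
~20:1 match-to-gap ratio used by mainstream collinearity tools (for
example MCScanX's 50:1) keeps chains extending through fractionated
regions. `gap_penalty = 0.05` follows that practice; all four parameters
are exposed.

On instances small enough to enumerate, the DP provably attains the
brute-force optimum (property-tested over 100 seeded anchor sets per run).

## Classification and depth ratios

A dominant one-to-one chromosome correspondence is computed by exact
maximum-weight bipartite matching (igraph) on summed block anchors. Blocks
are then labeled syntenic ("+" on a dominant pair), inversion ("-" on a
dominant pair), or translocation (non-dominant pair). A block whose rank
interval overlaps a higher-scoring block's interval by more than 50% *on
exactly one genome side* is a duplication: overlap on both sides is the
same region pair seen twice (for example an inverted segment nested inside
a syntenic span) and keeps its primary label.

The syntenic depth ratio counts, for every gene, the blocks whose rank
span covers it; the modal nonzero coverage per side is reported as a
ratio string. An unshared triplication reads "1:3" (each pre-event gene
covered by three blocks); sister genomes without an intervening
polyploidy read "1:1".

# Ka/Ks by NG86 counting

Coding-sequence divergence uses the Nei–Gojobori (1986) counting method.
Per codon, the synonymous site count is the synonymous fraction of all
nine single-nucleotide neighbours (averaged over the two sequences; stop
codons count as nonsynonymous targets, so S + N = 3 x codons). Differences
between codons are averaged over all minimal substitution pathways with
equal weights; pathways through a stop codon are excluded unless every
pathway is. Proportions are corrected for multiple hits with the
Jukes–Cantor formula `ks = -3/4 log(1 - 4 pS / 3)`; an argument at or
below zero sets a saturation flag instead of a value. The implementation
is table-driven (precomputed 64 x 64 pathway counts); tests check it
against an independent per-codon enumeration oracle for exact agreement
of S, N, Sd and Nd.

Alignment is protein-guided: translated sequences are globally aligned
(Needleman–Wunsch, affine gaps, BLOSUM62 by default) with
`Biostrings::pairwiseAlignment`, then back-translated to codon columns.
Codons containing N or a gap are excluded from all counts. NG86 with JC
correction was chosen over ML codon models because it is fully
specifiable and oracle-checkable; no 4DTv statistic and no ML estimation
are provided.

# Ks peak detection, rate correction, and dating

Ks values are filtered to a window (default 0.005–5: the lower bound
excludes allelic/tandem near-zero noise, the upper bound saturated
estimates) and log-transformed. Gaussian mixtures with 1..4 components
are fitted by EM (k-means initialisation, 10 seeded restarts per
component count; the likelihood is monotone by construction) and the
component count is selected by BIC. The mixture-on-log-Ks route gives
defensible peak locations and a principled one-vs-many peak decision;
tests cross-check the fit against mclust.

The peak attributed to the shared triplication is the component nearest a
prior location (default Ks 1.2, configurable); if two components fall
within 15% of each other around the prior the choice must be made
explicitly.

Lineages differ in synonymous rate, which displaces a shared event's peak.
Because rate scaling is linear in Ks, the correction is one multiplicative
factor per species, `f = peak_reference / peak_species`, applied to every
Ks value; the corrected peak coincides with the reference by construction
and a refit confirms it. Dating converts a peak to time with
`T = Ks / (2 r)`; the synonymous substitution rate `r` is always an
explicit input (with `r` in the commonly used range 4.7–5.3 x 10^-9
/site/year, a peak at Ks 1.22 dates to ~115–130 Mya).

# Gene retention

A reference gene is *retained* iff it is an anchor in at least one
collinear block. Retention is profiled in rank windows (default 100 genes,
step 50) and overall. The denominator is all reference genes by default —
the conservative, unambiguous choice — with an `in_block_only` switch to
restrict it to genes inside some block's span. With `step == window` the
windows partition each chromosome and the gene-count-weighted mean of
window fractions equals the overall fraction exactly (tested as an
identity).

# Ancestral karyotype reconstruction

The reconstruction is adjacency consensus with greedy linearization, in
the Dollo-flavoured tradition of ancestral gene-order tools:

1. **Partition.** The reference genome is cut at the union of all block
   boundaries from its pairwise comparisons; the resulting minimal
   segments are candidate ancestral blocks. Each segment is projected
   into every other species through the block anchors (orientation from
   the block); segments shorter than `min_block_genes` (default 10 —
   micro-blocks inflate breakpoints) or supported by fewer than two
   species are dropped and reported. Adding species only refines the
   segmentation; dropping one never does.
2. **Adjacency scoring.** Each species contributes one adjacency per pair
   of consecutive oriented blocks on a chromosome; the weight is the
   number of species exhibiting it. With a rooted species tree, an
   adjacency is an ancestral candidate only if observed on both sides of
   the root (Dollo criterion).
3. **Linearization.** Greedy maximum-weight matching on block extremities,
   rejecting edges that would reuse an extremity or close a cycle;
   connected paths are the CARs. Without a tree the default minimum
   adjacency weight is 2: a junction observed in a single genome cannot
   be polarized and would otherwise bake branch-private fusions into the
   ancestor. Ties break on (weight, extremity names); each CAR is
   emitted in the lexicographically canonical of its two readings, since
   a CAR's global orientation is arbitrary.

Per-branch rearrangements are classified against the reconstruction:
fusion/fission from chromosome-count bookkeeping (CARs present vs
chromosomes, after a dominant chromosome-to-CAR matching); an inversion
per maximal run of dominant-CAR blocks whose orientation is flipped
relative to the CAR (the majority relative orientation defines the
unflipped state, so CAR orientation does not matter); moved segments from
non-dominant CARs, with reciprocal pairs between two chromosomes counted
as one translocation each and unpaired moves as one each.

# The synthetic-data generator

The simulator emulates the history this kind of analysis infers: an
8-chromosome ancestor (100 genes per chromosome by default), an ancient
whole-genome triplication with per-copy i.i.d. gene loss (no fractionation
bias — the simplest null; bias would be a config extension), per-branch
inversions and reciprocal terminal translocations (fusions and fissions
available as explicit events), lineage-specific synonymous-rate
multipliers, and codon sequences evolved to a target NG86 Ks. Every run is
deterministic under its seed, gene content is conserved by all
rearrangements, and replaying the event log from the ancestor reproduces
each tip exactly.

Two generator choices deserve explanation:

* **Breakpoint separation.** Random events reserve a buffer (default:
  the 12-gene minimum segment length) around their breakpoints, shared
  across branches, so no two events place breakpoints within one block
  length of each other. Breakpoint reuse is a real phenomenon, but it
  makes individual events formally unidentifiable at block resolution;
  the generator's default regime is the one in which recovery is
  well-posed, and the minimum event size (12 genes) sits deliberately
  above the 10-gene ancestral-block resolution because a flanking
  collinear chain can absorb one boundary anchor of an inverted segment.
* **Sequence evolution and calibration.** Substitutions follow a
  K80-style jump process: Poisson event count, uniform site, transition
  drawn kappa-fold more often than either transversion, and events that
  would create a stop codon discarded. This makes the per-codon process
  an exactly analyzable 64-state uniformized Markov chain. The expected
  NG86 pS of a diverged pair is computed from that chain's transition
  matrix, and the event rate is solved (uniroot) so the predicted
  JC-corrected Ks equals the target — no Monte-Carlo tuning, and kappa
  is handled exactly. Residual bias of the *mean* estimate is the Jensen
  convexity of the JC correction (about +2% at Ks 1.22 with 300-codon
  genes, inside the documented 5% band); the lognormal peak location,
  which the pipeline actually uses, is affected less. A full codon model
  (and indels, and composition heterogeneity) is deliberately not
  simulated: only synonymous-distance recovery is needed, and the NG86
  estimator itself defines the truth scale.

What passing tests on these simulations do **not** show: robustness to
assembly errors, tandem arrays, missing annotations, biased fractionation,
or homolog lists with false pairs (a false-pair rate is not simulated by
default). Real-data runs should treat the depth-ratio histograms and the
rejects/dropped reports as first-line diagnostics.

# Problem sizes and numerical choices

The test-suite and the acceptance script run at desk scale, chosen so the
full suite completes in a few minutes: 8 x 100-gene genomes for synteny,
retention and karyotype recovery (10–20 seeded replicates), 120–150
sequence pairs of 300 codons per lineage for the rate-correction study,
and 2,000 draws for mixture recovery. EM stops at a log-likelihood change
below 1e-8 (500 iterations cap) with component standard deviations floored
at 1e-4 on the log scale; mixtures are refused below 50 values or at
near-zero variance rather than fitted unstably. Retention windows narrower
than 5 genes are refused for the same reason.

# A worked run

```{r}
library(syntevo)

# simulate a small clade with a shared triplication and run everything
res <- run_demo("demo_out", seed = 11)

# per-comparison depth ratios and Ks peaks
vapply(res$depth_ratios, `[[`, "", "ratio")
res$dating

# ancestral chromosomes and per-branch events
res$karyotype$karyotype
res$karyotype$branch_events
```

Stages are also available individually (`build_anchors`, `chain_anchors`,
`classify_blocks`, `estimate_depth_ratio`, `align_codons`, `ks_ng86`,
`fit_peaks`, `correct_rates`, `date_event`, `retention_profile`,
`partition_ancestral_blocks`, `score_adjacencies`, `linearize_cars`,
`classify_rearrangements`) and communicate through documented text
formats, so each is independently runnable and testable.

# Known limitations

* Rate correction is a single multiplicative factor per species; no
  finer (e.g. time-varying) rate model is attempted.
* The karyotype module reconstructs adjacencies, not event order along a
  branch, and computes no rearrangement distance (no DCJ).
* Retention profiles are rank-based; bp-resolution density tracks are out
  of scope.
* NG86 saturates above Ks ~2; deep events beyond that need slower-evolving
  markers than synonymous sites.
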