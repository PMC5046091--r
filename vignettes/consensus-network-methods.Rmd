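---
title: "Methods: consensus differential expression and signed regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus differential expression and signed regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnetcons)
```

# The problem and the model

Small case/control microarray studies of circulating miRNAs and genes
replicate poorly: platforms measure different (partially overlapping)
feature panels, cohorts are small, and per-study significance lists are
contaminated with false positives. `mirnetcons` treats the collection of
studies as the unit of analysis. Its statistical core is deliberately
plain — per-dataset two-sample t-tests and ratio-of-means fold-changes —
because the error control is supplied *across* datasets by two devices:

* a **directional consensus rule**: a feature is called only when
  significant (raw p ≤ α) in at least `k_min` datasets *and* changed in
  the same direction in all of those supporting datasets; and
* **permutation tests** that calibrate the consensus count against what
  random per-platform feature lists of the observed sizes would produce.

No per-dataset multiple-testing correction is applied, by design: raw
p ≤ α keeps per-dataset lists liberal, and the consensus-plus-permutation
machinery is what controls the aggregate error.

## Per-dataset differential expression

Intensities are assumed non-negative and on a linear scale (fold-change
is the ratio of group means, which only makes sense on linear
intensities); a `log2_input` flag exponentiates matrices stored in log2
on read. The t-test defaults to the Welch unequal-variance form —
cohorts from different platforms and tissues have no reason to share
variances — with the pooled Student form available via `var_equal`.
Degenerate features are resolved explicitly: identical values in both
groups give p = 1 and FC = 1 ("unchanged"); zero variance with unequal
means gives p = 0; a zero control mean leaves FC undefined, so the
feature is excluded from that dataset's table with a warning and is
recorded in an `excluded` attribute.

The implementation is vectorized (closed-form Welch statistic and
Satterthwaite degrees of freedom via `pt()`), and the test suite checks
it feature-by-feature against `stats::t.test()` on both the Welch and
Student paths.

## The consensus call

`consensus_select()` gives every feature seen in any dataset one row:
features missing from a platform simply lack that dataset's vote — no
imputation, and a feature measured on fewer than `k_min` platforms can
never pass. The direction criterion requires *all* supporting
(significant) datasets to agree. A consequence worth knowing: a feature
genuinely consistent in three datasets is spoiled if the fourth dataset
produces an opposite-direction false positive (probability roughly
α/2 per feature). This is intended — the rule reads "consistent in the
three or four experiments" strictly — and it caps directional-consensus
recovery slightly below 1 even for strong effects.

## The permutation tests

Two tests are run: overlap-only and directional. Each of B replicates
redraws, per dataset, a uniform random subset of that platform's
universe with the observed significant-set size, and counts features
drawn in ≥ `k_min` datasets. In the directional test a sampled feature
inherits the direction of its observed fold-change in that dataset:
directions are a fixed per-dataset labeling and only membership is
randomized, which preserves each dataset's up/down imbalance. (An
alternative `random_sign` mode assigns i.i.d. signs; it is exposed
because the choice is genuinely open, but inheriting observed signs is
the default.) The directional count can never exceed the overlap count
on the same draw, and the suite checks this replicate-wise.

The reported p-value is r/B; when r = 0 the test has hit its resolution
and reports the bound 1/B flagged as a bound (B = 5000 gives
"< 0.0002"). The conservative (r+1)/(B+1) estimator is available via
`conservative = TRUE`. Correctness is anchored two ways: the Monte-Carlo
mean of the null count is compared with an expectation enumerated
exhaustively over all choose(6,3)^4 subset combinations of four
6-feature universes, and under a fully null synthetic study the
empirical p-values over 200 independent studies are checked for
approximate uniformity (Kolmogorov–Smirnov). For the uniformity check
the test uses α = 0.3 on 1000-feature fully shared universes so the
count statistic has enough support for its discrete p-value grid to
approximate the uniform; that is a property-test configuration, not an
analysis default.

# Interaction databases and their cutoffs

Validated-target records pass only with causal evidence: TarBase-style
records require the method "reporter gene assay" (exact,
case-insensitive) because expression-correlation methods (microarray,
sequencing) do not demonstrate binding; miRTarBase-style records are
dropped when the support type is "weak" (case-insensitive; any other
value, including missing, counts as non-weak). Predicted targets must
pass, with *inclusive* boundaries, TargetScan context score ≤ −0.19,
microT-CDS miTG ≥ 0.993 and miRDB ≥ 84, and a pair must appear above
cutoff in all three databases. The synthetic interaction tables place
scores on both sides of — and exactly at — every boundary, and record
which pairs must survive, so the filters are pinned at their edges.

Curated TF–miRNA records carry an activation/repression sign and a
feedback flag; each flagged record contributes the reciprocal
miRNA → TF repression edge to the target set (deduplicated), mirroring
the biology of mutual TF/miRNA regulation.

# Promoter scanning with exact p-values

Promoter windows run from 1.5 kb upstream to 0.5 kb downstream of the
TSS (2 kb total), strand-oriented: minus-strand windows are
reverse-complemented so window coordinate 0 is always −1500 relative to
the TSS in transcript orientation. Windows beyond a sequence end are
N-padded with a warning. Coordinates are 0-based half-open throughout.

Scoring adds a pseudocount of 1e-3 to the motif probabilities
(renormalizing positions) and takes log2 odds against the motif file's
background. Scores are discretized once, at granularity
(score range)/1000, into integer steps; the exact null distribution of
the integer score of a random background string is computed by
position-wise convolution, and its tail is the match p-value. Scanner
and table operate on the same integer scores, so lookups are exact for
the discretized score; the suite verifies the DP tail against exhaustive
enumeration of all 4^L strings for motif lengths up to 6 at 1e-12.

Both strands are scanned (the reverse strand via the reverse-complement
matrix, so offsets stay in forward window coordinates); footprints
containing N or lowercase (repeat-masked) bases are skipped. Hits with
p ≤ 0.05 are kept — the per-match threshold is 0.05, not a stricter
scanner default, because 0.05 is the analysis' stated rule — reduced to
the best hit per (TF, target) pair, sorted by p with ties broken
lexicographically by TF then target, and the top
`ceiling(0.01 × n_pairs)` pairs retained. Deduplication before
truncation, and truncation applied per category (TF→miRNA separately
from TF→gene) where both arms are analysed, are documented choices: the
order of those two operations is not forced by the analysis definition,
and dedup-first makes the retained set independent of how many redundant
hits a pair produces.

# Network, signs and loops

Edges carry a category (`mirna_target`, `tf_mirna`, `tf_gene`), a sign
and an evidence level. Default signs encode the standing assumptions —
miRNAs repress their targets, TFs activate theirs — and explicit curated
records override them. One edge per ordered pair: validated + predicted
duplicates merge to evidence "both"; the same pair under two categories
is an error (it cannot arise under the role constraints); contradictory
explicit signs are an error naming the pair; self-loops are rejected.
Node roles (mirna / tf / target) derive from incident edge categories,
and a node may hold several (a TF that is also a miRNA target).

Feedback loops are simple directed cycles, positive iff the number of
repression edges is even. The default maximum length is 2 (mutual
regulation), which is the form curated TF/miRNA feedback pairs take;
longer cycles are available through `max_len` via a bounded
depth-first enumeration that starts each cycle at its smallest node so
every cycle is reported exactly once. Feed-forward loops are ordered
triples X→Y→Z with the shortcut X→Z, coherent iff
sign(X→Z) = sign(X→Y)·sign(Y→Z); the ordered-triple reading (rather than
unordered node sets) is the interpretation used throughout. Both
enumerations are validated against brute-force oracles on 100 random
signed digraphs.

# Enrichment and subnetworks

Over-representation uses the upper hypergeometric tail with the
background defaulting to the union of the collection's genes; query and
terms are intersected with the background first, and terms without query
overlap are skipped. Benjamini–Hochberg adjustment is the standard
step-up (delegated to `p.adjust(method = "BH")`), and terms at
FDR ≤ 0.05 are flagged enriched. Only gene symbols enter the query —
annotation collections describe genes, so miRNA nodes never count toward
the overlap k; miRNAs associate with terms through subnetwork adjacency
instead.

A term's subnetwork is: seed = term genes present in the network; nodes
= seed plus all in/out-neighbours; edges = the seed-incident network
edges. Whether edges *among* the neighbours belong in the subnetwork is
genuinely ambiguous in the analysis this mirrors — the seed-incident
reading is the default and the induced-subgraph alternative is available
via `include_neighbor_edges = TRUE`.

# The synthetic study generator

`simulation_spec()` defaults describe a four-platform blood miRNA study:
850 features per platform (miRNA arrays of the era measured fewer than
900 mature miRNAs), half of each platform shared across all platforms
and half platform-private, and case/control sizes 20/21, 59/37, 23/70
and 8/8 spanning the realistic range from small pilot studies to larger
cohorts. Intensities are lognormal — baselines lognormal(meanlog 5,
sdlog 1), samples scattering with log-scale sd 0.5, a realistic
between-subject spread for normalized arrays — and planted case effects
are multiplicative (× δ or ÷ δ, default δ = 2), so the ratio-of-means
fold-change targets δ. Three planted classes exercise every branch of
the consensus rule: 18 directional consensus features, 21 features
significant in ≥ 3 datasets with conflicting directions, 60 sporadic
features (≤ 2 datasets).

The generator does *not* emulate probe-level correlation structure,
batch effects, platform-specific noise or miRNA co-regulation along
genomic clusters; passing tests therefore show the machinery is correct
under an idealized independent-feature lognormal world, not that the
statistical power claims transfer to any particular real study design.

Fixture tables for interactions, motifs (12 sharp PWMs of length 8–12,
consensus-base probability 0.85), promoters (2 kb background sequence
with planted consensus sites and N-masked runs) and gene sets
(terms biased toward the genes that survive the target filters, so
enrichment has a detectable signal) are all pure functions of
(spec, seed). Promoters are named after the consensus miRNAs and the
surviving target genes, and a few curated TFs get sites planted both in
their regulated miRNA's promoter and in promoters of that miRNA's
targets, so the assembled network contains the TF→miRNA→target plus
TF→target co-regulation structure in which feed-forward loops live.

# Problem sizes and runtime choices

The test suite runs entirely on synthetic data at sizes chosen to keep
each property sharp but cheap: exhaustive PWM enumeration up to motif
length 6; loop oracles on 12-node graphs; the exhaustive permutation
expectation on four 6-feature universes; null-uniformity over 200
studies of 1000 features with B = 400; and recovery of 30 planted
consensus features at δ = 4, noise sd 0.2, 20 samples per group on
850-feature platforms — the configuration under which ≥ 90% directional
recovery is asserted. The full suite and the acceptance script each run
in well under a minute on one CPU.

# Known limitations

* The consensus rule conditions on raw per-dataset significance; it has
  no notion of effect-size heterogeneity and is not a meta-analytic
  estimator.
* Permutation p-values are bounded below by 1/B; very strong consensus
  is reported as a bound, not an estimate.
* The scanner's p-values are exact for the discretized score only;
  granularity (range/1000) makes the discretization error negligible
  relative to the 0.05 decision threshold, but scores are not
  continuous.
* Loop significance is not tested against randomized networks; the
  census is descriptive.
* Identifier mapping expects prepared one-to-many mapping tables; no
  alias-history resolution is attempted.
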