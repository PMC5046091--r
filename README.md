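# mirnetcons

Cross-dataset consensus differential expression and signed regulatory
network analysis for miRNA/gene microarray studies.

Individual case/control microarray studies of blood biomarkers — for
example in multiple sclerosis — are typically small, run on different
platforms with partially overlapping feature panels, and analysed with
different statistics, so their lists of differentially expressed (DE)
miRNAs and genes barely overlap. `mirnetcons` implements a consensus
strategy for this situation and the downstream regulatory-network
analysis it feeds:

1. **Per-dataset differential expression.** For each feature, a two-sided
   Welch t-test between cases and controls and the fold-change
   FC = mean(case) / mean(control); a feature is up-regulated when
   FC > 1, down-regulated when FC < 1.
2. **Directional consensus.** A feature passes the overlap criterion when
   it is significant (p ≤ α, default 0.05) in at least k (default 3) of
   the datasets, and the directional criterion when those supporting
   datasets also agree on the direction of change.
3. **Permutation tests.** The consensus count T is compared with a null
   built by redrawing, per dataset, a uniform random feature subset of
   the observed DE size from that platform's measured universe; with B
   replicates and r null counts ≥ T the reported p-value is r/B, or the
   resolution bound 1/B when r = 0 (so B = 5000 reports "< 0.0002").
4. **Target integration.** Validated miRNA-target records are kept only
   with causal support (reporter gene assay; non-"weak" support types);
   predicted records must pass fixed cutoffs in all three prediction
   databases (context score ≤ −0.19, miTG ≥ 0.993, score ≥ 84);
   feedback-flagged TF-miRNA records contribute reciprocal
   miRNA → TF repression edges.
5. **Promoter scanning.** 2 kb promoter windows (1.5 kb upstream to
   0.5 kb downstream of the TSS, strand-oriented) are scanned with PWMs;
   match p-values are exact tail probabilities of the discretized
   log2-odds score under the background, computed by dynamic programming;
   hits with p ≤ 0.05 are reduced to the best hit per (TF, target) pair
   and the top 1% of pairs is retained.
6. **Signed network and loops.** miRNAs repress their targets and TFs
   activate theirs unless a curated record says otherwise; feedback loops
   (simple cycles, default mutual regulation) are positive iff they
   contain an even number of repressions; feed-forward loops X→Y→Z with
   X→Z are coherent iff sign(X→Z) = sign(X→Y)·sign(Y→Z).
7. **Enrichment and subnetworks.** Hypergeometric over-representation of
   the network's gene nodes against a GMT collection, BH-adjusted
   (enriched at FDR ≤ 0.05); per-term subnetworks are the term's genes in
   the network, their first neighbours and the seed-incident edges, with
   miRNAs associated to terms by subnetwork membership.

A first-class synthetic-data module generates multi-platform studies
with planted consensus/inconsistent/sporadic signals, interaction tables
that straddle every filter boundary, and promoters with planted motif
sites, so the whole pipeline is testable without any downloads.

## Worked example

The `analysis/` directory holds the staged workflow; run the scripts in
order from the repository root:

```sh
Rscript analysis/01_simulate_study.R    # synthetic 4-dataset study
Rscript analysis/02_consensus_de.R      # DE, consensus, permutation tests
Rscript analysis/03_motif_scan.R        # promoter PWM scan
Rscript analysis/04_network_loops.R     # network assembly + FBL/FFL census
Rscript analysis/05_enrichment.R        # gene-set enrichment + subnetworks
```

Stage 2 prints, for the default simulated study (18 planted directional
consensus features among 850-feature platforms):

```
dataset1: 850 features, 100 DE at p<=0.05
dataset2: 850 features, 95 DE at p<=0.05
dataset3: 850 features, 93 DE at p<=0.05
dataset4: 850 features, 74 DE at p<=0.05
consensus: 40 features pass overlap (>=3 of 4), 18 also pass direction
Permutation consensus test: observed = 40, B = 5000, r = 0, p < 0.0002
Permutation consensus test: observed = 18, B = 5000, r = 0, p < 0.0002
```

i.e. the directional consensus recovers the 18 planted features, and no
null replicate reaches either observed count, so both tests report the
1/B bound. Stage 4 then reports the assembled signed network and its
loop census:

```
merged miRNA-target interactions: 69
after feedback-partner augmentation: 73
network: 83 nodes (mirna=18, target=59, tf=10), 91 edges (mirna_target=73, tf_gene=8, tf_mirna=10)
feedback loops: 4 (2 positive, 2 negative)
feed-forward loops: 6 (6 coherent, 0 incoherent; 6 containing a miRNA)
```

and stage 5 flags the two gene-set terms deliberately enriched in
network genes (q = 0.001 and 0.043) and writes the miRNA-by-term
presence matrix of their subnetworks.

Everything the scripts do is a thin layer over exported functions
(`differential_expression()`, `consensus_select()`,
`permutation_consensus_test()`, `filter_validated()`,
`filter_predicted()`, `scan_promoters()`, `assemble_network()`,
`find_feedback_loops()`, `find_feedforward_loops()`,
`hypergeometric_enrichment()`, `extract_subnetwork()`, ...), and
`run_pipeline()` executes all stages from a single config with one seed
and a hashed output manifest.

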