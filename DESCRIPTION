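Package: mirnetcons
Title: Consensus Differential Expression and Signed Regulatory Network
    Analysis for miRNA and Gene Microarray Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates differential expression results across multiple
    case/control microarray datasets by a directional consensus criterion
    (significant in at least k of the datasets, with a consistent direction
    of change), assesses the consensus by permutation tests that redraw
    feature sets of the observed sizes from each platform's measured
    universe, filters validated and predicted miRNA-target interactions at
    fixed database cutoffs, scans promoter windows with position weight
    matrices using exact dynamic-programming match p-values, assembles a
    signed directed regulatory network of miRNAs, transcription factors and
    targets, enumerates feedback and feed-forward loops with sign/coherence
    classification, and performs hypergeometric gene-set enrichment with
    Benjamini-Hochberg correction and term-centred subnetwork extraction.
    Includes a synthetic-data generator that emulates multi-platform
    case/control studies with planted consensus signals for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
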