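Package: repeatedit
Title: Quantification of Base-Editing Interruptions and Instability in Trinucleotide Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying base-editing outcomes in trinucleotide
    repeat (TNR) tracts from amplicon sequencing reads. Reads are anchored at
    repeat flanks, decomposed into in-frame triplets and classified against
    IUPAC degenerate edited-allele patterns (e.g. YAR for cytosine base editing
    of CAG repeats, GRR for adenine base editing of GAA repeats). Sample-level
    editing statistics are extrapolated to full-length alleles with a
    per-triplet probability model. Also included: somatic repeat-instability,
    expansion and contraction indices from fragment-analysis peak tables;
    per-locus off-target editing probabilities from treated/untreated pileup
    counts with PAM-anchored mismatch classification and codon consequence
    calls; a two-sample Kolmogorov-Smirnov comparison of interruption-count
    distributions; and a synthetic-data generator that makes every pipeline
    stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
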