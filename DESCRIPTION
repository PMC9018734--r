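Package: wtpe
Title: Design and Outcome Quantification for Bi-Directional Prime Editing
    with Nuclease Cas9
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for prime editing with nuclease wild-type Cas9 (WT-PE),
    which couples a double-strand break with a 3' extended single-strand flap
    to write large genomic changes. Designs single pegRNAs and C1/C2 pegRNA
    pairs for targeted deletions and chromosomal translocations, predicts the
    exact expected edited alleles and their characteristic indel archetypes,
    classifies merged amplicon sequencing reads into the accurate-edit,
    edit-with-indel and pure-indel outcome classes, and quantifies editing
    efficiency from gel densitometry tables and absolute qPCR standard
    curves. A built-in simulator generates amplicon reads, gel lanes and
    qPCR tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
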