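Package: brackenlite
Title: Bayesian Reestimation of Taxonomic Abundance from Kraken-Style
    Read Classifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates species-level (or any taxonomic level) abundances
    from k-mer LCA read-classification reports in the style of the Bracken
    abundance estimator.  Reads that a Kraken-type classifier strands at
    higher taxonomic nodes, because their sequence is shared among several
    near-identical genomes, are redistributed down to the target level
    with Bayes' theorem, using per-genome read-destination probabilities
    obtained by self-classifying every length-r sliding window of every
    reference genome against the same database.  Includes a minimal exact
    canonical k-mer to LCA index, an NCBI-dialect taxonomy parser,
    readers/writers for Kraken report and k-mer distribution files, a
    seeded mock-community simulator for validation, and the standard
    evaluation metrics (average relative error, false-positive rate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
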