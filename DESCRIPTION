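Package: repeatarch
Title: Repeat Architecture Analysis of Circular Organelle Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the repeat architecture of small circular
    organelle genomes such as algal mitochondrial DNA. Discovers tandem
    arrays, dispersed repeat families and inverted repeats, decomposes
    repeat regions into a small alphabet of named units with copy-number
    and identity statistics, tiles regions into unit arrangements and
    detects palindromic arrangements, scores stem-loop (hairpin) potential
    and GC-skew inflection points, and compares gene content and gene
    order (synteny blocks, inversions, translocations) across strains.
    Includes a synthetic-genome simulator that plants known architectures
    with machine-readable truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
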