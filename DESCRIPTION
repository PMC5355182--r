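Package: rareset
Title: Rareness Coefficients and Minimal Core Collections from Bulked SSR Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing landrace germplasm collections genotyped as
    bulked SSR (microsatellite) samples scored as a binary marker/allele
    presence matrix. Computes a per-accession coefficient of rareness (the
    mean squared deviation of an accession's marker/allele scores from the
    collection-wide means), selects a minimal core collection covering every
    marker/allele combination with the deterministic rareness-seeded AMA
    ("All Marker Alleles") greedy algorithm, and provides the supporting
    diversity and association analyses: Euclidean distances at bulk and
    accession level, within/between-accession distance tests, UPGMA trees
    with Newick export, jackknife column-exclusion sensitivity, geographic
    versus genetic distance correlation, race and kernel-colour association
    by Welch t-tests and G-statistic contingency tests with
    Benjamini-Hochberg FDR control, and forward-selection regression of
    altitude on marker/allele scores. A seeded simulator of bulked
    genotyping provides ground truth for recovery tests, together with the
    closed-form probability of detecting an allele in a DNA bulk.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    vegan,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
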