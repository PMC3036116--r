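Package: penetrance
Title: Penetrance Estimation in Autosomal Dominant Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the penetrance rate K of a rare autosomal dominant
    allele from pedigree phenotype data by maximum likelihood, with an exact
    Bayesian credible interval computed from the normalized likelihood under
    a uniform prior.  Pedigrees are decomposed into the likelihood-relevant
    structures (affected carriers, obligate non-penetrant carriers, childless
    normal offspring of carriers, trees of normal descendants, same-sex twin
    pairs and consanguineous loops); consanguineous loops are split into
    transmission configurations whose estimates are combined by
    inverse-variance weighting.  Per-individual heterozygosity probabilities
    and offspring risks are computed for genetic counseling.  Includes a
    gene-drop simulator, LINKAGE/PED input and output, a compact
    structure-counts text format, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
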