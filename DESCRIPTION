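Package: sutura
Title: Cranial Suture Contact Phenetics and Morphological Parsimony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for coding, comparing and analysing the sutural contacts
    between skull bones. Implements a categorical coding scheme for bone
    contacts (six spatial relations, four ordered suture-depth levels), a
    taxon-by-taxon percentage similarity statistic over contact tables, a
    seeded simulator of contact evolution along a phylogeny, assembly and
    patching of morphological character matrices (NEXUS and TNT dialects,
    ordered characters, taxon deactivation), and a maximum-parsimony engine
    with Fitch and ordered (linear-cost) character lengths, consistency and
    retention indices, exhaustive and random-addition plus
    tree-bisection-reconnection heuristic search under backbone constraints,
    and strict consensus. Ships a four-taxon turtle contact table transcribed
    from published anatomical descriptions as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
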