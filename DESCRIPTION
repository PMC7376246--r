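Package: karyoevo
Title: Single-Cell Karyotype Clonal-Evolution Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing tumor clonal evolution from per-metaphase
    spectral karyotyping (SKY) data and matched binned whole-genome copy-number
    profiles. Provides a data model for metaphase karyotypes with structural
    events (nonreciprocal and reciprocal translocations, fusions, rings),
    whole-genome-duplication calling from chromosome counts, clonality and
    clonal-NRT acquisition classification, event-weighted pairwise distances
    with neighbor-joining phylogenies rooted on a euploid outgroup,
    founder-clone identification and parsimony ordering, a Monte-Carlo null for
    inter-lineage NRT sharing, L1-distance trees and shared/private segment
    trees from 10-kb binned copy-ratio profiles, exact Fisher tests for small
    contingency tables, and a forward simulator of karyotype evolution with
    full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'event-notation.R'
    'accessors.R'
    'ploidy.R'
    'distance.R'
    'nj.R'
    'clones.R'
    'cnv.R'
    'karyo-io.R'
    'stats.R'
    'simulate.R'
    'sharing.R'
    'pipeline.R'
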