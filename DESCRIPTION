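Package: OMVscreen
Title: Genome-Wide Outer Membrane Vesiculation Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide dot-blot screens of outer
    membrane vesicle (OMV) production in arrayed bacterial knockout
    libraries. Converts per-well densitometry intensities into
    membrane-normalized, replicate-averaged log10 vesiculation scores;
    performs growth quality control by fitting modified Gompertz curves to
    OD600 time series and excluding strains with poor fits or outlying
    maximum growth rates; calls over- and under-vesiculation phenotypes by
    a two-standard-deviation rule; tests functional categories for
    hypergeometric enrichment among significant strains; and quantifies
    concordance between the high-throughput screen and orthogonal
    flask-grown culture OMV preparation (FCOP) measurements. A synthetic
    data generator emulating the plate structure, replicate design and
    noise of such screens provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'blot-quant.R'
    'concordance.R'
    'enrichment.R'
    'growth-qc.R'
    'io.R'
    'methods.R'
    'phenotype-call.R'
    'pipeline.R'
    'synthetic-data.R'
    'utils.R'
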