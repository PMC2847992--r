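Package: respflux
Title: Degree of Respiration, Enzyme Abundances and Transcription-Factor
    Inference from 13C Flux and GFP-Reporter Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline linking the functional degree of
    respiration in budding yeast to transcriptional regulation. Estimates
    specific growth rates and uptake/secretion rates from batch-culture
    time courses, corrects GC-MS mass-isotopomer distributions of
    protein-bound amino acids for natural isotope abundance and unlabeled
    biomass, infers ratios of converging fluxes from 13C labeling
    patterns, solves a constrained stoichiometric model for net fluxes
    and the uptake-normalized respiratory TCA flux (degree of
    respiration), quantifies enzyme abundances from GFP/biomass slopes of
    reporter strains, calls differential expression across carbon
    sources, and ranks candidate transcription factors by the upper-tail
    hypergeometric probability that their curated targets overlap the
    differential enzymes. Includes a synthetic-data generator with known
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
biocViews: Metabolomics, GeneRegulation, NetworkInference, Proteomics
RoxygenNote: 7.3.3
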