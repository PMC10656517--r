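Package: immunopepR
Title: Post-Identification Immunopeptidomics Workflow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the computational workflow that follows database search in
    HLA immunopeptidomics: classification of proteolytic-degradation artifacts via
    per-peptide coverage and ligand-propensity scores, two-component Gaussian-mixture
    EM deconvolution and FDR-derived thresholds; spectral validation of eluted
    peptides (including neoepitopes) by b/y fragment-ion matching and correlation
    against isotope-labelled synthetic peptide spectra; assembly of benign reference
    peptidomes and comparative tumor-exclusivity and presentation-frequency
    profiling; physicochemical peptide characterization (monoisotopic mass, GRAVY
    hydropathy, HLA population coverage); and seeded synthetic-immunopeptidome
    generators with ground-truth bookkeeping for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
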