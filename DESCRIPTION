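Package: apscreen
Title: Diagnostic-Ion Screening of Anabaenopeptins and Protease
    Inhibition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based annotation of anabaenopeptin (AP) and
    cyanopeptolin-like peptides in positive-mode LC-MS/MS spectra of
    solid-phase-extraction fractions, together with quantification of
    enzyme inhibition from plate-reader absorbances. Provides a
    monoisotopic mass engine for residues and diagnostic ions (the Lys
    marker at m/z 84, immonium ions, Arg-related ions), an
    anabaenopeptin scaffold model (five-residue ring with conserved Lys
    plus a ureido-linked exocyclic residue) with in-silico fragment
    prediction, an MGF reader/writer with tolerance-based peak matching,
    a screener that gates on the Lys marker ion, infers the exocyclic
    residue from its neutral loss and names novel analogs by nominal
    mass, dose-response fitting (linear, loglinear, quadratic) with
    IC50 extraction and relative-potency statistics, and seeded
    simulators for spectra, decoys and assay plates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'apscreen-package.R'
    'inhibition.R'
    'mass-calculus.R'
    'scaffold-library.R'
    'spectra-io.R'
    'screener.R'
    'simulate.R'
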