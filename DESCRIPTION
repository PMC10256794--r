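Package: wmcoupling
Title: Structure-Function Coupling of White-Matter BOLD and Intracranial
    EEG Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the coupling between white-matter BOLD
    functional connectivity, band-limited stereotactic-EEG (SEEG)
    functional connectivity, and streamline-count structural connectivity
    defined on depth-electrode contacts. Implements SEEG conditioning
    (Butterworth broadband and power-line filters, white-matter common
    average reference, segment averaging), seven-band decomposition,
    Pearson and coherence functional connectivity, sphere-ROI BOLD
    extraction with lightweight temporal preprocessing, streamline
    counting between contact spheres, distance-residualized Spearman
    coupling with Benjamini-Hochberg FDR across participants and bands,
    and a synthetic multimodal study generator with known ground-truth
    coupling for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
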