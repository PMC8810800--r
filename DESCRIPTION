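Package: bacnavsim
Title: Simulation of Engineered Bacterial Sodium Channels in Cardiac Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-silico platform for evaluating prokaryotic voltage-gated
    sodium channels (BacNav) as a cardiac gene therapy. Implements a
    Hodgkin-Huxley kinetic model of the engineered NavSheP D60A channel and
    inserts it into adult ventricular myocyte models (O'Hara-Rudy human;
    Luo-Rudy-lineage guinea pig). Provides single-cell pacing and clamp
    protocols, peak-current calibration of expression levels, monodomain
    simulation of action potential propagation in 1D cables and 2D tissues
    with nonconducting fibrotic obstacles, a transmural Brugada-syndrome
    cable with pseudo-ECG readout, and action potential feature extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
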