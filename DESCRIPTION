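Package: notchcrypt
Title: Lateral Inhibition and Notch Positive Feedback in the Intestinal Crypt Niche
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of juxtacrine Notch-Delta signaling
    circuits in the intestinal stem-cell niche. Implements dimensionless ODE
    models of lateral inhibition (LI) with and without a direct Notch positive
    feedback (PFLI), single-cell input-output and bifurcation analysis,
    pair-cell fixed-point censuses and bistability maps, multicell maximum
    Lyapunov exponent (MLE) patterning maps on periodic lattices,
    deterministic patterning dynamics, and a stochastic cellular Potts model
    of the crypt base coupling per-cell Notch ODEs to growth, division,
    adhesion and anoikis.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
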