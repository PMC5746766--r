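Package: ramanforms
Title: Simulated and Experimental Raman Analysis of Dopamine Molecular Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing quantum-chemical vibrational calculations with
    surface-enhanced Raman (SERS) measurements of dopamine. Reads vibrational
    mode tables from quantum-chemistry frequency output or tab-separated files,
    converts Raman scattering activities to relative intensities using the
    frequency-fourth-power and thermal population factors, applies harmonic
    frequency scaling, and synthesizes broadened spectra with Lorentzian line
    shapes. Experimental SERS time series can be read, averaged, normalized and
    baseline-corrected. Calculated and measured band positions are paired by an
    optimal one-to-one matching with residual statistics, and spectra are
    classified against marker-band profiles of the dopamine molecular forms
    (neutral, cationic, anionic, zwitterion-like, and dopaminequinone). A
    synthetic-data generator provides ground-truthed mode tables and noisy SERS
    time series for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
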