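Package: piva
Title: Peripheral Intravenous Analysis of Venous Pressure Waveforms During CPR
Version: 0.1.0
Authors@R: person("PIVA", "Maintainers", email = "piva@example.org", role = c("aut", "cre"))
Description: Tools for extracting the amplitude of chest-compression-frequency
    oscillations from peripheral venous pressure waveforms recorded during
    cardiopulmonary resuscitation (PIVA), using non-overlapping fixed-length
    FFT windows. Includes detectors for the PIVA amplitude peak and the
    end-tidal CO2 doubling event, coronary perfusion pressure and per-cycle
    arterial metrics, quarter-segmented hemodynamic summaries, event-timing
    statistics relative to return of spontaneous circulation (mean +/- SE,
    Shapiro-Wilk screening, uncorrected Fisher's LSD comparisons), and a
    seeded synthetic CPR-recording generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
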