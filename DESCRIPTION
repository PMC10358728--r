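Package: huecancel
Title: Artificial Hue-Cancellation Experiments and a Change-of-Basis Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates classical hue-cancellation psychophysics with trivial
    (identity or linear) observer networks operating in different tristimulus
    representations (cone-like LMS, opponent ATD, linear and display RGB).
    Quasi-monochromatic stimuli are synthesized on a wavelength grid, the
    matching problem is solved per wavelength by preconditioned gradient
    descent (with a minimum-norm closed-form oracle for linear observers), and
    the four cancellation-light weight functions are assembled into red-green
    and yellow-blue valence curves. A change-of-basis model expresses the same
    curves analytically from the color matching functions and a basis built on
    the cancellation lights, enabling fast error-surface scans over alternative
    cancellation-light choices that locate the optimum at the classical
    blue/green wavelengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
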