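Package: vfatau
Title: Variable Flip Angle T1 Mapping via the Half-Angle Tangent Linearization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal relaxation time (T1) and amplitude mapping
    from spoiled gradient-echo variable flip angle (VFA) data using an exact
    algebraic form of the Ernst signal equation. The half-angle tangent
    transform of the flip angle, tau = 2*tan(alpha/2), and the hyperbolic
    tangent transform of the relaxation term, rho1 = 2*tanh(TR/(2*T1)), turn
    the Ernst equation into a low-order rational function, so that plotting
    y = S/tau against x = S*tau places ideal data on a straight line with
    y-intercept equal to the signal amplitude and slope -1/(2*rho1).
    The package provides the transforms, linear and nonlinear estimators
    (single-TR, dual-angle, multi-TR and the conventional sin/tan comparator),
    first-order noise propagation with correlated coordinates, numerically
    optimized minimal-variance flip-angle schedules, transmit-field (B1) bias
    application and correction, data-driven detection of signal bias
    (imperfect spoiling, slice-profile and Rician-floor deviations),
    a synthetic phantom generator, and vectorized voxelwise map fitting with
    NIfTI input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
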