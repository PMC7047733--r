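Package: ivtflow
Title: Geometry, Hemodynamics and Design-of-Experiments Analysis of the
    Intraventricular Tunnel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the geometric configuration of the
    intraventricular tunnel (IVT) constructed during double-outlet right
    ventricle (DORV) repair controls the trans-tunnel pressure difference.
    Builds parametric tunnel centerlines and watertight swept lumen meshes
    (STL/PLY export) from three surgical factors (VSD-to-valve distance,
    ejection angle, turning radius); computes the pressure difference with a
    reduced-order minor-loss model calibrated against a 25-run balanced
    orthogonal experiment; performs balanced three-factor main-effects ANOVA
    with Fisher-LSD pairwise comparisons; and sweeps the turning radius to
    locate the plateau beyond which the pressure difference changes by less
    than a chosen percentage per step. A synthetic-data generator with known
    main effects and noise supports power and type-I-error studies of the
    statistical machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
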