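Package: graftnih
Title: Multiscale Simulation of Neointimal Hyperplasia in Vein Bypass Grafts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduced-order multiscale framework for predicting neointimal
    hyperplasia (NIH) in peripheral vein bypass grafts. Pulsatile inflow
    waveforms with two-element Windkessel outlet models and Carreau-Yasuda
    shear-thinning blood rheology yield wall shear stress time series along
    the graft; shear indices (TAWSS, OSI, HOLMES) drive a coupled
    ordinary-differential-equation model of smooth muscle cell, collagen,
    growth factor and nitric oxide dynamics that grows the intima, narrows
    the lumen, and reports percentage area stenosis at the anastomoses.
    Includes centerline geometry metrics (curvature, torsion, tortuosity),
    synthetic data generators, and an import contract for wall shear fields
    computed by external 3D CFD solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
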