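Package: hnflow
Title: Micropolar Hybrid-Nanofluid Boundary-Layer Flow over a Curved
    Stretching Surface
Version: 0.1.0
Authors@R:
    person("hnflow", "maintainers", email = "hnflow@example.org",
           role = c("aut", "cre"))
Description: Simulator for the unsteady magnetised Powell-Eyring micropolar
    blood-based hybrid-nanofluid bioconvection boundary layer over a porous
    curved stretching surface.  Provides volume-fraction mixture closures for
    the effective properties of two-particle hybrid nanofluids, the coupled
    dimensionless similarity system (momentum, microrotation, energy,
    bacterial density) with pressure recovery, a damped-Newton collocation
    solver with parameter continuation on a graded mesh, a numerical
    homotopy-analysis-method (HAM) solver with h-bar convergence control,
    and engineering quantities (skin friction, Nusselt number, nutrient
    concentration number) with parameter-sweep and validation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
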