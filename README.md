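# hnflow

Simulator for the unsteady magnetised Eyring–Powell **micropolar
blood-based hybrid-nanofluid** boundary layer over a **porous curved
stretching surface**, with bioconvecting bacteria. It is aimed at
researchers in computational biofluid dynamics who need a reproducible,
testable implementation of this family of similarity models: mixture
property closures, the coupled dimensionless BVP, a collocation solver, a
numerical homotopy-analysis (HAM) solver, engineering quantities and
parameter sweeps.

## The model in brief

A similarity transformation `eta = r sqrt(a/(nu_f (1-ct)))` reduces the
boundary-layer PDEs to a coupled two-point BVP in the stream function
`f(eta)`, microrotation `g(eta)`, temperature `theta(eta)` and bacterial
density `chi(eta)`:

* momentum (4th order): curved viscous operator
  `f'''' + 2f'''/(eta+K) - f''/(eta+K)^2 + f'/(eta+K)^3`, Lorentz/Darcy
  sink `(sigma_r M + mu_r beta0)(f'' + f'/(eta+K))`, Eyring–Powell cubic
  terms (`alpha1`, `alpha2`), micropolar coupling `-K1(g'' + g'/(eta+K))`,
  convection and unsteadiness (`gamma`);
* microrotation, energy (Joule heating `M Pr Ec f'^2`, variable
  conductivity `beta`), and bacterial density (`Lb`, `lambda`, `Omega`);
* wall: `f(0)=0, f'(0)=1, theta(0)=chi(0)=1, g(0) = -m0 f''(0)`;
  far field: decay of all fields.

Engineering outputs: skin friction
`Cf Re^(1/2) = -[(mu_r+K1+alpha1) S - (alpha2/3) S^3]` with
`S = f''(0) + f'(0)/K`, Nusselt number `-theta'(0)` and
nutrient-concentration number `-chi'(0)`.

In the flat Newtonian limit (`K = Inf`, extras off) the model collapses to
the classical MHD stretching sheet `f''' + f f'' - f'^2 - M f' = 0` with
the exact solution `-f''(0) = sqrt(1+M)` — the package's validation
anchor.

## Worked example

```r
library(hnflow)

## classical magnetised flat sheet, M = 1
prof <- solve_flow(classical_limit_params(1))
print(prof)
#> <hnf_profile> 201 nodes on [0, 15]; max residual 1.24e-09
#>   -f''(0) = 1.414214   -theta'(0) = 3.352216   -chi'(0) = 0.103254
engineering_quantities(prof)
#> CfRe^(1/2) = 1.414214   NusRe^(-1/2) = 3.352216   NnsRe^(-1/2) = 0.103254
```

`-f''(0) = 1.414214` is `sqrt(2)` to 7 digits — the exact closed form of
the magnetised Crane problem. The Nusselt number 3.35 is the wall heat
flux of a Pr = 21 (blood) boundary layer on the clean flat sheet.

```r
## the full curved hybrid-nanofluid model (Au + TiO2 in blood at 1% each)
rat <- mixture_ratios(volume_fractions(0.01, 0.01))
print(rat)
#> <mixture_ratios> mu_r=1.0518 rho_r=1.16802 rhocp_r=0.99415 k_r=1.06066 sigma_r=1.06122
base <- solve_flow(flow_params(), rat)   # documented default base, K = 0.3
engineering_quantities(base)
#> CfRe^(1/2) = 0.218849   NusRe^(-1/2) = -0.195937   NnsRe^(-1/2) = 1.066935
```

The 1% gold/titania loading raises viscosity by 5% and conductivity by
6%. The negative Nusselt number is real model behaviour, not a bug: at
blood Prandtl number with unsteadiness the printed energy equation
suppresses conductive wall flux and Joule/viscous heating dominates (see
the methods vignette, "Honest limitations").

```r
## validation: literature benchmarks, closed forms, HAM vs collocation
validation_report(ham_order = 20)

## h-bar convergence-control curve for the HAM series
hbar_curve(ham_validation_params(), quantity = "fpp0",
           hbar_range = seq(0.2, 1.0, by = 0.1), order = 10)
```

A command-line interface with `solve`, `sweep`, `validate` and
`hbar-curve` subcommands is available via `hnflow_cli()` (wrapper script
in `inst/scripts/hnflow`).

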