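---
title: "Methods: the curved-surface micropolar hybrid-nanofluid model and its solvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the curved-surface micropolar hybrid-nanofluid model and its solvers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnflow)
```

# The physical model

`hnflow` simulates the unsteady, two-dimensional boundary layer of a
blood-based hybrid nanofluid over a porous curved stretching surface of
radius $R$, with three rheological/transport extensions that are standard
in the hemodynamics modelling literature:

* **Eyring–Powell stress** (a $\sinh^{-1}$ shear law, linearised to cubic
  order; dimensionless parameters $\alpha_1$, $\alpha_2$),
* **micropolar microrotation** $N$ (dimensionless $g$) coupled to the
  shear through the material parameter $K_1$,
* **bioconvecting bacteria** described by a reaction–diffusion equation
  for the scaled density $\chi$ with growth rate $\lambda$ and density
  difference $\Omega$,

together with a transverse magnetic field ($M$), Darcy drag ($\beta_0$),
Joule/viscous heating ($Ec$, with electrical conductivity of the mixture),
temperature-dependent thermal conductivity ($\beta$), and the
$1/(1-ct)$ unsteadiness scaling ($\gamma = c/a$).

A similarity transformation $\eta = r\sqrt{a/\nu_f(1-ct)}$ collapses the
governing PDEs to a coupled two-point boundary-value problem in
$f(\eta)$ (stream function), $g(\eta)$ (microrotation), $\theta(\eta)$
(temperature) and $\chi(\eta)$ (bacterial density):

* a **fourth-order momentum equation** whose viscous block is the
  curved-surface operator
  $f'''' + 2f'''/(\eta+K) - f''/(\eta+K)^2 + f'/(\eta+K)^3$, with the
  Lorentz/Darcy sink acting on the shear group $S = f'' + f'/(\eta+K)$,
  the Eyring–Powell cubic terms, the micropolar coupling
  $-K_1(g'' + g'/(\eta+K))$, convection, and the unsteady
  $\gamma$-terms;
* a **second-order microrotation equation**
  $(\mu_r + K_1/2)(g'' + g'/(\eta+K)) + \tfrac{K}{\eta+K}(fg' - f'g)
  - K_1(2g + f'' + f'/(\eta+K)) - \tfrac{\gamma}{2}(\eta g' + 3g) = 0$;
* an **energy equation**
  $k_r[(1+\beta\theta)(\theta'' + \theta'/(\eta+K)) + \beta\theta'^2]
  + \sigma_r M \,Pr\,Ec\, f'^2
  + (\rho c_p)_r Pr\,[\tfrac{K}{\eta+K} f - \tfrac{\gamma\eta}{2}]\theta' = 0$;
* a **bacterial-density equation**
  $\chi'' + \chi'/(\eta+K)
  + Lb\,[\tfrac{K}{\eta+K} f - \tfrac{\gamma\eta}{2}]\chi'
  + \lambda(\Omega + \chi) = 0$.

Boundary conditions: $f(0)=0$, $f'(0)=1$, $\theta(0)=\chi(0)=1$,
$g(0) = -m_0 f''(0)$ at the wall and
$f'=f''=\theta=\chi=g=0$ as $\eta \to \infty$.  The published source
system prints $g(0)=0$, the strong-concentration limit; the package makes
the wall-slip constant $m_0 \in [0,1]$ configurable with default 0.  A
pressure field $P(\eta)$ is recoverable algebraically from a converged
profile (`recover_pressure()`).

Two transcription choices deserve note (both flagged where they occur in
the source): the curved Laplacian of the bacterial equation is implemented
with $\chi'/(\eta+K)$ (the printed source shows $\chi/(\eta+K)$, a clear
typo), and the Eyring–Powell cubic group is implemented term-by-term as
printed, with the flat steady limit pinned to
$\frac{d}{d\eta}\left[f''' + ff'' - f'^2 - Mf'\right] = 0$ — the
classical MHD stretching-sheet equation, whose exact solution
$f = (1-e^{-m\eta})/m$, $m=\sqrt{1+M}$, anchors every validation in the
package.  The exact grouping of the cubic $\alpha_2$ terms is ambiguous in
the source at three places; alternative groupings change the skin friction
at large $\alpha_2$, which is why $\alpha_2$ defaults to a small value.
The pressure expression's $\alpha_2$ term is implemented with the printed
token order ($+\alpha_2 S^2 (f''' + f''/(\eta+K) - f'/(\eta+K)^2)$); a
$-\alpha_2/3$ reading is arguable from the wall-stress series.

## Mixture closures

Effective properties of the two-particle suspension enter only through
five dimensionless ratios (`mixture_ratios()`): Brinkman viscosity
$(1-\phi_1-\phi_2)^{-2.5}$, linear mixture rules for density and
volumetric heat capacity, and a two-particle Maxwell closure for thermal
and electrical conductivity with the effective particle conductivity
$\bar k = (\phi_1 k_1 + \phi_2 k_2)/\Phi$.  At $\Phi = 0$ the Maxwell
form is $0/0$ and the exact limit 1 is returned by a dedicated branch;
note the closure approaches 1 with slope
$3(\bar k - k_f)/(\bar k + 2k_f) \le 3$, i.e. linearly in $\Phi$, so
"continuity at $\Phi \to 0$" holds at the $O(\Phi)$ level and no tighter.
The built-in material registry ships gold, titanium dioxide and blood
constants; the heat-capacity rule uses each particle's own $\rho c_p$
(the printed table repeats one subscript — with that literal reading the
second particle's heat capacity would never be used).

# Parameters, defaults and what they mean

| parameter | meaning | default | rationale |
|---|---|---|---|
| `K` | dimensionless surface radius | 0.3 (0.1 in sweeps) | sweep anchor printed in the source tables; `Inf` = flat sheet |
| `K1` | micropolar material parameter | 0.2 | small two-way coupling |
| `alpha1`, `alpha2` | Eyring–Powell linear/cubic | 0.1, 0.01 | cubic kept small (grouping ambiguity above) |
| `M`, `beta0`, `gamma` | magnetic, Darcy, unsteadiness | 0.1 | printed sweep anchors |
| `beta` | variable conductivity | 0.1 | small |
| `Ec` | Eckert number | 0.1 | small; see the heat-flux degeneracy below |
| `Pr` | Prandtl number | 21 | the standard blood value |
| `Lb`, `lam`, `Omega` | bioconvection Lewis, growth, density difference | 0.1 | printed sweep anchors |
| `m0` | microrotation wall slip | 0 | printed wall condition $g(0)=0$ |

These defaults are a documented baseline, **not** the (unpublished)
values behind the source's figures and tables; exact numeric reproduction
of those tables is out of scope by design.

# The collocation solver

`solve_flow()` discretises the ten-component first-order system with the
3-stage Lobatto IIIA scheme (the `bvp4c` "Simpson with Hermite midpoint"
form, 4th-order accurate at the nodes), assembles the block-bidiagonal
Newton matrix as one sparse matrix, and iterates damped Newton with Armijo
backtracking to a residual tolerance of $10^{-8}$.  Hard parameters
($M, \alpha_2, K_1, \gamma, \beta_0, Ec, \beta, \lambda$) are ramped from
zero in a fixed number of continuation stages, bisecting stages that fail.
Everything is deterministic.

Meshes are sinh-graded toward the wall; for strongly curved surfaces
($K < 1$) the grading is steepened by $-\log K$ because the
$1/(\eta+K)$ coefficients put solution structure on the scale of $K$
itself.  Two further mesh facts matter:

* **Far-field corner layer.**  For $\gamma > 0$ the energy and bacterial
  equations acquire an anti-damped convective coefficient
  $\sim \gamma\eta/2$ far afield, so the exact solution approaches a
  plateau and the truncated boundary condition cuts it to zero across a
  layer of width $\approx 2k_r/((\rho c_p)_r Pr\,\gamma\,\eta_\infty)$
  (analogously with $Lb$ for $\chi$).  The mesh appends a geometric tail
  cluster sized from this estimate; without it Newton fails for
  $Pr\,\gamma \gtrsim 4$.  The layer is a truncation artifact and has no
  effect on wall quantities (the backward influence decays like
  $e^{-Pr\gamma(\eta_\infty^2-\eta^2)/4}$).
* **Flat sentinel.**  $K = \infty$ replaces $1/(\eta+K)$ by 0 and
  $K/(\eta+K)$ by 1 exactly; no large finite $K$ is ever used.

`solve_reduced_flat()` solves the third-order classical problem directly
and Richardson-extrapolates $-f''(0)$ from meshes $N$ and $2N-1$; against
the closed form $\sqrt{1+M}$ it is accurate to $\sim 10^{-9}$.
`residual_report()` returns both the discrete collocation residuals
(which honour the Newton tolerance) and pointwise equation residuals of a
spline interpolant on a $3\times$ finer grid; the latter are dominated by
the $O(h^4)$ discretisation error, not by the Newton tolerance, and are
diagnostic only.

# The homotopy-analysis solver

`ham_solve()` implements the order-by-order deformation recursion
$L[u_m - \chi_m u_{m-1}] = \hbar R_m$ with the printed initial guesses
($f_0 = 1-e^{-\eta}$, $\theta_0=\chi_0=e^{-\eta}$, $g_0$ rescaled to the
configured wall condition) and auxiliary operators.  The printed operator
list contains an internal contradiction: it shows a second-order
$L_f = f'' - f'$ while attributing to it the kernel
$c_1 + c_2e^{-\eta} + c_3e^{\eta}$, which belongs to the third-order
$f''' - f'$.  The package follows the kernel (third order), which also
supplies exactly the three boundary constraints each deformation order
needs.  $R_m$ is extracted exactly (to round-off) by evaluating the
nonlinear operators on the partial series at $3(m-1)+1$ complex roots of
unity and taking a discrete Fourier transform — the nonlinearities are
polynomial of degree 3 in the embedding parameter per order, so this is
the exact Taylor coefficient, not a finite-difference estimate.

Two solution paths share this recursion:

* **Flat configurations** use an exact exponential–polynomial algebra:
  every deformation component lies in
  $\mathrm{span}\{\eta^j e^{-n\eta}\}$, products are 2-D coefficient
  convolutions, and the $L$-inverses are closed-form per-term recurrences
  (including the secular $n=1$ resonances).  This is a double-precision
  replica of the pen-and-paper recursion; it was verified to 9
  significant digits against an independent exact-rational symbolic
  implementation at order 12.
* **Curved configurations** represent components on a grid and solve each
  order as a linear two-point BVP with the prefactored collocation
  operator (the $1/(\eta+K)$ coefficients are not closed in any
  exponential basis).

**The sign of $\hbar$.**  A mode analysis (and the symbolic oracle)
shows that with $L_f = f''' - f'$ and $f_0 = 1-e^{-\eta}$ the series for
the magnetised problem **diverges for every $\hbar < 0$**: corrections
carry a far-field plateau ($f_m(\infty) \ne 0$), and the plateau mode is
amplified by $1 + |\hbar|/2$ per order.  The admissible plateau of the
$\hbar$-curve lies at **positive** $\hbar$ ($\approx +0.3$ to $+0.5$ at
$M=1$), where the series converges to the collocation solution
($|{-f''(0)} - \sqrt 2| \approx 5\times10^{-4}$ at order 25).  The
truncation bias of this series at moderate order ($-f''(0) \approx
1.4187$ at order 12) closely matches the deviation of published
"present results" values from $\sqrt{1+M}$ in the benchmark table —
strong evidence that those values are truncated-series output of exactly
this recursion.  `hbar_curve()` scans any range; `hbar_plateau()` picks
the flattest point; `ham_solve()` raises an error (or records the order,
with `on_divergence = "continue"`) when the residual grows by more than
20% for three consecutive orders.

**Validation configuration.**  `ham_validation_params()` is the
classical flat $M=1$ benchmark configuration with *passive* microrotation
($K_1 = 0$, $m_0 = 0.5$: $g$ is driven by $f''$ through its wall
condition and convection but does not feed back) and transport fields
that decay on the $O(1)$ similarity scale ($Pr = 2$, $Lb = 2$,
$\lambda = 0$) — the qualitative regime the published validation tables
display (all four profiles decay to $\sim 10^{-4}$ by $\eta = 10$).  This
choice is forced, not cosmetic: with two-way coupling ($K_1 > 0$) the
$f$–$g$ iteration diverges for every fixed $\hbar$ pair we scanned, and
for $\lambda > 0$ the bacterial equation admits **no decaying far field
at all** (see below), so neither belongs in a convergence benchmark.  At
order 20 with plateau $\hbar_f$ and $\hbar_g = -1$ the HAM-vs-collocation
errors are $\max|f'| \approx 3\times10^{-4}$ and
$\max|g| \approx 5\times10^{-4}$.

# Honest limitations of the stated parameter world

These are properties of the printed equations at the documented baseline,
established by measurement and by the analyses above; the corresponding
directional acceptance assertions are deliberately left failing rather
than tuned around:

* **Wall heat flux degeneracy.**  For $Pr\,\gamma > 0$ the energy
  equation forces $\theta'(\eta) \propto e^{+Pr\gamma\eta^2/4}$ far
  afield, so a bounded solution must have an exponentially tiny wall
  gradient: without dissipation the Nusselt number is numerically **zero**
  at blood Prandtl number, and with $Ec > 0$ it is **negative**
  (dissipation-dominated).  The published positive, $O(1)$ Nusselt
  numbers that decrease with $M$ and $\gamma$ and are flat in $\beta_0$
  to four decimals cannot be produced by the printed equation at
  $Pr = 21$, $\gamma \ge 0.1$ under any $Ec$.
* **Bacterial far field.**  With $\lambda > 0$ the far-field equation
  $\chi'' + \lambda\chi = -\lambda\Omega$ (flat, $\gamma=0$) has
  oscillatory non-decaying solutions, and for $\gamma > 0$ the decaying
  branch disappears entirely (algebraic growth); moreover on a truncated
  domain the operator crosses an eigenvalue near
  $\lambda \approx (\pi/\eta_\infty)^2 + O(Lb)$, so the printed sweep
  values $\lambda \in \{0.1, 0.2, 0.3\}$ straddle a resonance and the
  responses to $\lambda$ and $\Omega$ are large and non-monotone, unlike
  the $10^{-4}$-level monotone drifts in the published table.
* **Skin friction vs curvature.**  At the documented base the wall shear
  group $S = f''(0) + f'(0)/K$ grows in magnitude with $K$, so the
  reported skin friction increases along the printed $K$ sweep, opposite
  to the published direction (whose underlying baseline is unknown).

What a green test here establishes: the transcribed equations (pinned by
independent transcription oracles at $10^{-10}$), the classical limits
(pinned by closed forms and the benchmark table at $10^{-3}$ relative),
the solver's internal convergence (mesh halving below $10^{-6}$ on wall
quantities), and the HAM recursion (pinned by the symbolic oracle).  What
it does not establish: agreement with the source's unpublished parameter
choices, or physical plausibility of the printed energy/bacteria
equations in the blood regime.

# Numerical choices summary

* Newton tolerance $10^{-8}$ (max-norm over collocation + boundary
  residuals); continuation in 6 stages with up to 6 bisections.
* Default domain $[0, 15]$, 201 nodes, sinh grading 3 (steepened for
  $K<1$, tail-refined for $\gamma>0$); `adapt_domain()` accepts a length
  when growing it by 1.5 changes the skin friction by under $10^{-6}$.
* Mixture closures branch exactly at $\Phi = 0$.
* The momentum equation is solved for $f''''$ only where its coefficient
  $(\mu_r + K_1 + \alpha_1 - \alpha_2 S^2)$ stays away from zero;
  otherwise an informative error suggests reducing $\alpha_2$.
* HAM: order default 15, $\hbar$ defaults $-1$ (override via
  `hbar_curve()`; the flat-path plateau is positive, see above);
  uniform grid, 301 nodes.
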