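---
title: "Models and methods behind ivtflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ivtflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtflow)
```

# The problem

After double-outlet right ventricle (DORV) repair, left-ventricular blood
reaches the aorta through a surgically constructed intraventricular tunnel
(IVT) running from the ventricular septal defect (VSD) to the aortic valve
orifice. The pressure difference ΔP across that tunnel is the clinical
criterion for tunnel stenosis (ΔP > 10 mmHg indicates outflow-tract
obstruction), and the tunnel's geometry is under the surgeon's control.
`ivtflow` studies how three geometric factors — the VSD-to-valve distance
D_SA, the ejection angle A_LT, and the turning radius R_TT — control ΔP,
using a balanced 25-run orthogonal experiment, main-effects ANOVA with
Fisher-LSD comparisons, and a single-factor turning-radius sweep.

# Idealized tunnel geometry

The centerline lives in a fixed right-handed frame: x horizontal, y
vertical towards the aortic-valve plane, z out of plane. It starts at the
VSD centre (origin) heading at A_LT degrees above horizontal, follows an
optional inlet straight of length `l_in`, turns through a circular arc of
radius R_TT spanning `θ = 90° − A_LT` until vertical, and ends with a
straight outlet run of length

$$L_{out} = D_{SA} - l_{in}\sin A_{LT} - R_{TT}\cos A_{LT}$$

on the plane `y = D_SA`, normal to it. `R_TT = 0` degenerates the arc into
a sharp elbow. A configuration is *feasible* iff `L_out ≥ 0`; infeasible
geometry raises a typed error carrying the deficit.

Two conventions here were genuinely open and are package design choices:

* **A_LT reference axis.** A_LT is measured between the inlet jet and the
  valve plane (horizontal), so `A_LT = 0` gives a full 90° bend and larger
  angles give gentler bends. This convention makes the bend severity — and
  hence the modelled ΔP — decrease monotonically with A_LT, which matches
  the ordering of the measured A_LT group means in the packaged 25-run
  experiment (6.55, 6.34, 4.48, 3.56, 1.69 mmHg at 0°…40°).
* **Inlet straight.** `l_in = 0` by default: the VSD opens directly into
  the bend. No measured value exists for an inlet run; it is configurable
  and enters the feasibility formula above.

The lumen diameter is not a measured quantity either. The default,
13.33 mm, is derived from the flow regime: with blood density
1050 kg/m³, viscosity 0.0035 Pa·s and inlet velocity 1 m/s,
`Re = ρvD/μ ≈ 4000` exactly when `D ≈ 13.33 mm`, the transitional regime
expected in the tunnel at peak systole. It is a named argument everywhere.

## Surface meshes

`build_surface_mesh()` sweeps a circle along the sampled centerline. For a
planar path the fixed out-of-plane binormal is exactly the
rotation-minimizing frame, so rings never twist. Caps are triangle fans
about the ring centroid; the capped mesh is closed (every edge shared by
exactly two triangles). Because the circle's centroid travels the
centerline, the exact swept volume is `π(d/2)²·L` by Pappus' theorem; the
discretized tube underestimates it by the inscribed-polygon factor
`(m/2π)·sin(2π/m)` — about 0.16% at the default 64 circumferential points,
comfortably inside the 2% acceptance band, and the axial step (default
0.5 mm) contributes far less. The mesh construction refuses
self-intersecting input (`R_TT < d/2` on a non-zero bend, including the
`R_TT = 0` miter), where the inner wall would fold. STL (binary per the
80-byte-header/little-endian convention, and ASCII) and ASCII PLY writers
are built in; binary STL stores float32, so one round trip quantizes
coordinates and is byte-stable thereafter.

# The reduced-order pressure model

The original experiment obtained ΔP per configuration from steady 3-D CFD.
This package deliberately replaces that stage with a one-dimensional
minor-loss surrogate — closed-form, deterministic and desk-verifiable:

$$\Delta P = \left(K_{ent} + K_{bend} + K_{exit} + f\,\frac{L}{D}\right)
  \tfrac12 \rho v^2, \qquad
  K_{bend} = c_1\left(\frac{\theta}{90}\right)^2
  e^{-c_2 R_{TT}/D},$$

converted at 133.322 Pa/mmHg. The entrance and exit coefficients stand for
the physiological steps at the VSD and the valve orifice, which are not
meshed. The friction factor is laminar `64/Re` up to Re 2000, Blasius
`0.316 Re^{-1/4}` from Re 4000, linearly interpolated in Re between — a
conventional bridge across the transitional gap that keeps `f` continuous.
The bend law is finite at the miter limit (`K = c_1` at θ = 90°,
R_TT = 0), vanishes for a straight run, and decays exponentially as the
bend is eased, which is what produces a plateau in the radius sweep.

Defaults `k_entrance = 0.5`, `k_exit = 1.0`, `c1 = 1.2`, `c2 = 2.0` are
conventional hydraulics magnitudes (sharp-edged entry, full jet discharge,
miter-bend loss). `calibrate_rom()` refits `(c1, c2, k)` (entrance and
exit shared during fitting) to measured responses by Levenberg–Marquardt
(`minpack.lm::nls.lm`, non-negativity bounds, `ftol = ptol = 1e-12`,
500 iterations max, started from the supplied coefficients — deterministic
for a fixed start). Constant responses are flagged as a degenerate fit
rather than an error. The surrogate's contract is *qualitative*: ΔP
strictly decreasing in R_TT and A_LT, weakly increasing in D_SA, rank
correlation with the measured 25-run responses — not pointwise CFD
equivalence, which no closed form can claim given that the original
turbulence closure is unspecified.

# Design of experiments and the statistics

The 25-run experiment is a balanced L25(5³) orthogonal array: each factor
level occurs exactly 5 times and each ordered cross-factor level pair
exactly once. `verify_balance()` checks both properties by brute-force
counting and reports every violation with row indices.
`construct_balanced_design()` builds fresh arrays by the Latin-square
index rule `C = (A + 2B) mod 5`, which satisfies both properties for any
level labels.

`ivt_anova()` uses the balanced closed form: per factor
`SS = Σ_l T_l²/5 − G²/25` on 4 df, error by subtraction on 12 df,
`F = MS_factor / MS_err`, P from the upper tail of F(4, 12). In a balanced
array type I and type III sums of squares coincide, so this is *the*
main-effects decomposition; the test suite cross-checks it against
`stats::aov` to 1e−8 on random balanced designs, and a 10,000-shuffle
permutation test on the packaged responses brackets the parametric
P-value for R_TT within Monte-Carlo error. Zero-variance responses return
P = 1 with a `zero_variance` flag rather than an exception; noise-free
responses with signal return P = 0 (infinite F) for the non-null factors.

`lsd_pairwise()` implements Fisher's LSD exactly: the pooled 12-df error
mean square, `SE = √(2·MS_err/5)` (identical for all pairs in a balanced
design), two-sided P from t(12), and *no* multiplicity adjustment. Fisher's
LSD was chosen over Tukey/Bonferroni because it is the procedure that
reproduces the published pairwise P-values for this experiment; two
published cells (0.379 for 5 vs 7.5 mm and 0.032 for 2.5 vs 5 mm) are
inconsistent with their own mirrored cells and with recomputation from the
published responses, and are treated as errata. Similarly, the published
ANOVA table's SS/F values and the A_LT P-value of 0.263 cannot be derived
from the published per-run responses; the package follows the responses,
from which P(D_SA) = 0.459 does reproduce.

# The turning-radius sweep and the plateau rule

`single_factor_sweep()` evaluates ΔP at radii `start, start+step, …`
(default 0–11 mm in 1 mm steps, 12 models), holding D_SA and A_LT at a
base configuration (which the original study left unstated; it is an
explicit argument here). The *change rate* is defined as the backward
relative difference, `100·|ΔP_i − ΔP_{i−1}|/ΔP_{i−1}` percent — the
published analysis plots but never defines it. The *plateau radius* is the
smallest swept value from which **every** subsequent step stays below the
threshold (default 5%), not merely the first quiet step; this tie-break
avoids false plateaus on noisy curves, and makes the plateau monotone
non-increasing in the threshold. Infeasible radii are dropped with a
warning; fewer than two feasible points is an error. On the analytic curve
`ΔP(r) = 2 + 6·exp(−r/2)` the rule returns 8 mm at the 5% threshold, the
worked oracle used in the tests. For the default loss coefficients the
exponential bend decay guarantees a finite plateau for every feasible base;
the finding that easing the bend beyond roughly 6 mm stops paying is a
qualitative contract here, since the underlying sweep values were published
only as a figure.

# Synthetic data: what it does and does not emulate

`generate_response()` draws `y = μ + a_i + b_j + c_k + ε`,
`ε ~ N(0, σ²)`, on a balanced design, with each factor's five level
offsets constrained to sum to zero (identifiability) and offsets assigned
by level rank. It deliberately contains **no interactions** — matching the
main-effects model being tested — and Gaussian noise, a choice, since the
numerical "noise" of a CFD response surface (discretization error plus
unmodelled interactions) is not characterizable from published information.
Consequently, passing simulations certify the statistical machinery
(type-I error within [0.03, 0.07] at α = 0.05; power ≥ 95% for a
4σ-range effect; `E[SS] = 5·Σoffsets² + 4σ²`), not the behaviour of the
ANOVA on real CFD output with lurking interactions. Reproducibility is by
R's Mersenne-Twister stream: one seed, bit-identical responses on any
platform. `generate_sweep_curve()` emulates the sweep's shape as
exponential decay to an asymptote plus optional noise.

Problem sizes used throughout the suite — 2000 null replicates, 500 power
replicates, 100 random designs for the oracle cross-check, 10,000
permutation shuffles — were chosen to put Monte-Carlo error well inside
the asserted bands while the whole suite stays interactive.

# Numerical choices and degenerate inputs

* Units are mm/degrees/mmHg at every interface; SI only inside the flow
  formulas. The mmHg conversion is pinned at 133.322 Pa/mmHg.
* Centerline endpoints are computed in closed form, so the end lies on the
  valve plane to machine precision (asserted at 1e−9 mm).
* Typed conditions (`ivtflow_infeasible_geometry`,
  `ivtflow_self_intersection`, `ivtflow_unbalanced_design`, …) let callers
  and the CLI distinguish failure modes; the CLI maps them to distinct
  exit codes.
* `run_experiment()` isolates per-row infeasibility (NA response plus a
  failure record) and aborts only when every row fails.
* CSV output is pinned to a fixed dialect (header
  `model,d_sa_mm,a_lt_deg,r_tt_mm,delta_p_mmhg`, `.` decimal, LF endings)
  so fixtures compare byte-for-byte.

# Package shape

The package follows the classic R modelling idiom per stage: a constructor
or fitting function returning a classed S3 object (`ivt_anova`, `ivt_lsd`,
`ivt_rom`, `ivt_sweep`, `ivt_design`) with `print`, `summary`, `coef`,
`predict`, `fitted`, `residuals` and `plot` methods where they are
meaningful. There is no single grand fitting function because the science
is a pipeline — geometry → flow surrogate → designed experiment → ANOVA →
sweep — and each stage is independently useful.

# Known limitations

* The flow surrogate is one-dimensional: no velocity/pressure fields, no
  turbulence modelling, no fluid–structure interaction, valves or moving
  walls, and steady flow only (peak systole). Only trend agreement with
  3-D CFD is claimed, and only within the clinically relevant radius range.
* The centerline is planar; out-of-plane tunnels are not modelled.
* Volumetric meshing (tetra/prism) and patient-specific CT reconstruction
  are out of scope; the surface mesh is an exchange artifact, not a CFD
  grid.
* The statistics are specific to the balanced 5-level, 3-factor array;
  unbalanced data are rejected rather than handled by general
  least-squares machinery, and interaction terms are not fitted.
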