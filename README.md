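# ivtflow

Geometry, hemodynamics and design-of-experiments analysis of the
**intraventricular tunnel (IVT)** constructed during double-outlet right
ventricle (DORV) repair.

In DORV, both great arteries arise from the right ventricle and the
ventricular septal defect (VSD) is the left ventricle's only outlet. Repair
routes left-ventricular blood through a surgically constructed tunnel from
the VSD to the aortic valve orifice. The trans-tunnel pressure difference
ΔP is the main postoperative criterion for tunnel stenosis: ΔP above
10 mmHg indicates left-ventricular outflow tract obstruction. This package
is for cardiovascular biomechanics researchers and surgical planners who
want to study — on a desk, with fully reproducible code — how three
geometric factors of the tunnel control ΔP:

* **D_SA** — distance from the VSD to the aortic-valve plane (mm),
* **A_LT** — ejection angle of blood entering the tunnel (degrees),
* **R_TT** — turning radius of the tunnel bend (mm).

## What it computes

**Parametric geometry.** `tunnel_params()` → `build_centerline()` builds
the idealized planar centerline (inlet jet at angle A_LT, circular arc of
radius R_TT spanning `θ = 90° − A_LT`, straight outlet run ending on the
valve plane), and `build_surface_mesh()` sweeps a circular lumen along it
into a watertight triangulated surface (STL/PLY export via `write_mesh()`).

**Reduced-order hemodynamics.** `pressure_difference()` evaluates a
one-dimensional minor-loss model,

    ΔP = (K_entrance + K_bend + K_exit + f·L/D) · ½ρv²,

with `K_bend = c1·(θ/90)²·exp(−c2·R_TT/D)`, the Darcy friction factor `f`
at the tunnel Reynolds number (≈ 4000 at the defaults: blood density
1050 kg/m³, viscosity 0.0035 Pa·s, inlet velocity 1 m/s, lumen 13.33 mm),
and 1 mmHg = 133.322 Pa. `calibrate_rom()` least-squares-fits the free
coefficients against measured responses.

**Design of experiments and statistics.** `table1_design()` ships the
canonical 25-run balanced L25(5³) orthogonal experiment with its CFD ΔP
responses; `construct_balanced_design()` and `verify_balance()` build and
brute-force-check balanced arrays. `ivt_anova()` performs the balanced
three-factor main-effects ANOVA (each factor on 4 df against the pooled
12-df error), and `lsd_pairwise()` the Fisher-LSD pairwise comparisons.

**Turning-radius sweep.** `single_factor_sweep()` evaluates ΔP over radii
0, 1, …, 11 mm and `plateau_radius()` applies the plateau rule: the
smallest radius from which every subsequent per-step relative change of ΔP
stays below 5%.

**Synthetic data.** `generate_response()` and `generate_sweep_curve()`
produce balanced-design responses with known main effects plus Gaussian
noise, and exponential-decay sweep curves, so type-I error and power of the
statistical machinery can be verified by simulation.

## Worked example

```r
library(ivtflow)

fit <- ivt_anova(table1_design())
fit
#> Main-effects ANOVA (balanced L25 orthogonal design)
#>
#>             SS df      MS       F        P
#> d_sa    7.5980  4  1.8995  0.9704 0.459000
#> a_lt   81.9032  4 20.4758 10.4602 0.000694
#> r_tt   77.7510  4 19.4377  9.9299 0.000875
#> error  23.4900 12  1.9575      NA       NA
#> total 190.7422 24      NA      NA       NA
```

The VSD-to-valve distance explains almost nothing (P = 0.459), while the
turning radius is strongly significant (P < 0.001): tunnel curvature, not
tunnel length, drives the pressure drop. Pairwise LSD comparisons localise
the effect at small radii:

```r
lsd_pairwise(fit, "r_tt")
#> Fisher-LSD pairwise comparisons for r_tt (pooled MS_err = 1.958, 12 df)
#>
#>  level_1 level_2 mean_diff     se     t     p
#>      0.0     2.5     3.094 0.8849 3.497 0.004
#>      0.0     5.0     3.988 0.8849 4.507 0.001
#>      0.0     7.5     4.634 0.8849 5.237 0.000
#>      0.0    10.0     4.838 0.8849 5.467 0.000
#>      2.5     5.0     0.894 0.8849 1.010 0.332
#>      ...
#>      7.5    10.0     0.204 0.8849 0.231 0.822
```

A sharp elbow (R_TT = 0) differs from every eased bend; beyond 2.5 mm the
differences are no longer significant. A single configuration predicts:

```r
pressure_difference(tunnel_params(d_sa = 20, a_lt = 20, r_tt = 7.5))
#> Trans-tunnel pressure difference: 7.094 mmHg (Re = 3999)
#>   breakdown (mmHg): entrance 1.969, friction 0.260, bend 0.928, exit 3.938
```

and the turning-radius sweep locates the plateau where further easing of
the bend stops paying:

```r
sw <- single_factor_sweep(tunnel_params(d_sa = 30, a_lt = 0, r_tt = 0))
sw$plateau_value
#> [1] 3
```

(The per-step change rate of ΔP falls below 5% from 3 mm onward for the
default loss coefficients; the plateau location depends on the bend-decay
coefficient `c2`.)

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/ivt.R", package="ivtflow"))') \
    reproduce-paper --out-dir out/
```

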