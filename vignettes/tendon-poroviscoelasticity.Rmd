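---
title: "A fibre-reinforced poroviscoelastic model of tendon: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fibre-reinforced poroviscoelastic model of tendon: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonpve)
```

## The model

`tendonpve` treats tendon as a fluid-saturated biphasic mixture. The total
Cauchy stress partitions into the solid-skeleton stress and the pore
pressure,

$$\sigma_{total} = \sigma_f + \sigma_m - p\,I,$$

with $\sigma_f$ the collagen-fibre stress, $\sigma_m$ the non-fibrillar
(proteoglycan) matrix stress and $p$ the pore pressure. The three
constituents map onto tendon composition: ~70% water, a dense axial
collagen network that dominates tensile load bearing, and a soft isotropic
matrix.

**Collagen fibres.** Each integration point carries a one-dimensional
fibre aligned (initially) with the tendon axis. The fibre model is a
modified standard linear solid: an exponential tension-only spring
($P_1 = E_1(e^{k_1\varepsilon_f}-1)$ for $\varepsilon_f > 0$) in parallel
with a Maxwell element whose spring is also exponential
($P_2 = E_2(e^{k_2\varepsilon_e}-1)$) and whose dashpot has constant
$\eta$. The fibre strain is logarithmic, $\varepsilon_f = \ln\lambda$,
with $\lambda = |F e^0|$ the stretch of the fibre direction pushed
forward by the deformation gradient. Eliminating the internal Maxwell
strain analytically and discretising the resulting stress balance with
backward Euler turns the update into a quadratic equation
$P_f^2 + bP_f + c = 0$ whose positive root is the new fibre stress
(`fibre_update()`).

A note on the constant term $c$: re-deriving the discrete quadratic from
the continuous fibre balance gives

$$c = -\tfrac{\eta}{k_2\Delta t}P_f^t
      - (P_1 + \eta\dot\varepsilon_f)(E_2 - P_1)
      - \tfrac{\eta}{k_2}\dot P_1,$$

i.e. the history term $P_f^t$ enters with a *negative* sign. Only this
form has the physically required fixed point — at zero strain and stress
rates the quadratic's positive root is exactly $P_1$, so a held stretch
relaxes to the equilibrium spring and stays there. The package implements
the derived form; the tests pin the fixed point, the quadratic-root
identity (residual below $10^{-9}$ relative), monotone relaxation, the
rate-independent limit ($\Delta t \to \infty$ recovers $P_1$) and
non-negative dissipation over closed strain cycles.

All rate terms use consistent backward differences over the step,
$\dot\varepsilon_f = (\varepsilon_f^{t+\Delta t}-\varepsilon_f^t)/\Delta t$
and likewise for $\dot P_1$. When $\varepsilon_f \le 0$ the fibre is slack:
its stress is zero and the stored viscous history is reset to the
stress-free state, which prevents a spurious tensile history from acting
on recontact. The spring exponent $k_1\varepsilon_f$ is capped at 200
(with a warning) so that optimiser excursions remain finite.

**Non-fibrillar matrix.** A compressible neo-Hookean solid with energy

$$W = \tfrac{K_m}{2}\left(\tfrac12(J^2-1) - \ln J\right)
    + \tfrac{G_m}{2}\left(\mathrm{tr}\,C - 3\det(C)^{1/3}\right),$$

whose exact push-forward is
$\sigma_m = \tfrac{K_m}{2}(J - 1/J)I + \tfrac{G_m}{J}(FF^T - J^{2/3}I)$,
with $K_m = E_m/(3(1-2\nu_m))$ and $G_m = E_m/(2(1+\nu_m))$. The closed
form is verified in the tests against a central-difference push-forward of
`strain_energy()` at random admissible deformation gradients (relative
tolerance $10^{-5}$).

**Fluid.** Darcy flow $w = -(k/\gamma_w)\nabla p$ with void-ratio
dependent conductivity $k = k_0\,((1+e)/(1+e_0))^{M_k}$. Because the
solid constituent is intrinsically incompressible, $(1+e)/(1+e_0) = J$
and the implementation uses $k = k_0 J^{M_k}$. The initial void ratio
comes from the water mass fraction via
$n_f = \rho_s n_{f,m} / (1-n_{f,m}+n_{f,m}\rho_s)$, $e_0 = n_f/(1-n_f)$.
The water mass fraction is not a calibrated quantity; the default 0.70
reflects the canonical "tendon is about 70% water" composition and is
configurable. The fluid specific weight $\gamma_w = 9.81\times10^{-6}$
N/mm$^3$ converts hydraulic conductivity (mm/s) into Darcy mobility; it
is the standard soils convention and is likewise configurable.

## Parameters

Nine constants are calibrated: $E_1, E_2, k_1, k_2, \eta$ (fibres),
$k_0, M_k$ (fluid), $E_m, \nu_m$ (matrix). `reference_params()` ships the
calibrated sets for the average tendon (load cycles 1-3 and 10-12) and the
nine specimen-specific fits; the cycle 1-3 average set
($E_1 = 0.023$ MPa, $E_2 = 0.443$ MPa, $k_1 = 40$, $k_2 = 31.06$,
$\eta = 609.34$ MPa·s, $k_0 = 1.19\times10^{-7}$ mm/s, $M_k = 0.96$,
$E_m = 0.77$ MPa, $\nu_m = 0.35$) is the default everywhere. Units are
fixed package-wide: mm, s, N, MPa, mm/s.

## The finite-element solver

The tendon is an axisymmetric cylinder (average geometry: length 8.4 mm,
cross-section 1.63 mm$^2$). The meridian rectangle is meshed with a
structured grid of 4-node quadrilaterals carrying equal-order bilinear
displacement and pore-pressure interpolation (the CAX4P element family),
2×2 Gauss quadrature. Kinematics are evaluated in the current
configuration, which is exactly equivalent to a total-Lagrangian
pull-back; the hoop stretch is $r/R$.

The discrete system stacks quasi-static momentum balance of
$\sigma_{total}$ (with axisymmetric hoop terms, no body forces) and
backward-Euler fluid mass balance
$\dot J/J + \nabla\cdot w = 0$. Boundary conditions mirror the tensile
test: the base is encastre (clamp), the axis is confined radially, the
outer surface is traction-free with $p = 0$ (free draining), and the top
edge carries either a prescribed axial displacement or a prescribed dead
axial traction. Two choices the experimental description leaves open are
exposed as configuration with these defaults: the top nodes are also fixed
radially (both ends are clamped in the machine), and the clamped ends and
the axis are impermeable (natural condition), so fluid drains only through
the free outer surface.

Each implicit step is solved by damped Newton iteration. The Jacobian is
built by finite differences with graph colouring: on a structured grid,
nodes three apart in each direction share no element, so all columns of
one colour are formed from a single residual evaluation — 27 evaluations
per Jacobian regardless of mesh size. The tests verify the coloured
Jacobian against a naive dense finite-difference Jacobian. Convergence
requires the momentum and mass residual blocks to drop below
`newton_rtol` ($10^{-8}$) relative to the step's initial residual, with
absolute floors; a negligible Newton increment (`incr_tol`) also counts
as converged, which matters at very small time steps where the $1/\Delta t$
storage term puts the mass residual at its roundoff floor. Non-convergent
steps are bisected in time recursively. Fibre histories are committed
only on convergence.

Numerical choices and their justification:

* **Mesh resolution** defaults to 4×16 elements (radial × axial). The
  tests show the reaction-force trace changes by less than 2% under
  refinement to 8×32 on a load-unload excursion to the 20 N peak.
* **Element family.** Equal-order u-p interpolation can show mild
  pressure oscillations near drainage boundaries when
  $\Delta t \ll h^2/c_v$; the loading rates simulated here stay out of
  that regime, and the consolidation benchmark bounds the error.
* **Initial state** is stress-free and drained ($p=0$, $e=e_0$); the
  experimental 1 N preload is part of the protocols (the first loading
  ramp), not an initial stress.
* **Verification.** (i) A patch test: a homogeneous drained stretch on
  one element reproduces the material-point stress times the current area
  to $10^{-6}$ relative. (ii) Terzaghi's consolidation problem (fibres
  disabled, confined column, small step load, drainage at the loaded end):
  the pore-pressure profiles match the analytic series to better than 2%
  at $T_v \in \{0.1, 0.5, 1.0\}$ on a 1×32 mesh. (iii) Global fluid
  conservation: the change in tissue volume equals the discrete boundary
  flux to $10^{-8}$ relative at tight solver tolerances. (iv) Time
  refinement: halving the default step changes the force trace by <1% of
  the peak.

The assembly kernels and the Newton loop are compiled (Rcpp/Armadillo); a
pure-R reference residual (`tendonpve:::fem_residual_r`) implements the
same physics through the exported constitutive functions, and the tests
require both residuals to agree to $10^{-12}$ on random states, so the
compiled path is pinned to the documented R implementation.

## Virtual experiments

* `strain_stiffening()`: displacement ramps at 0.05-1.0 mm/s. All rates
  share one amplitude — the displacement at which the 0.1 mm/s ramp
  reaches the 20 N cycle peak (found by within-step bisection), the
  package's reading of a ramp "to the first load peak". With the average
  cycle 1-3 parameters this amplitude is about 1.27 mm (15% strain).
* `compute_modulus()`: the "linear region" of a convex tension curve is
  operationalised as the least-squares slope where stress lies in the
  60-90% of peak window (configurable); stress is nominal (F/A$_0$),
  strain engineering (U/L), the usual tensile-test conventions.
* `stress_relaxation()`: 2-10% strain at 0.1 mm/s, 300 s hold on a
  geometrically growing time grid; `relaxation_rate()` fits the log-log
  slope over hold times 1-100 s and reports it as a positive decay rate.
* `creep_test()`: dead tractions of 1-3 MPa held 500 s, then 0.2 MPa for
  another 500 s; strain is the top-edge displacement over the length.
* `horizontal_fibre_test()`: the relaxation protocol with fibres rotated
  to the radial direction, so axial stretch never tensions them — the
  response isolates the biphasic matrix.
* `cycle_decomposition()`: one 1-20 N cycle; at the probe element
  (outermost element at mid-height, matching the reported output
  location) it reports the matrix share of the peak total axial stress
  and the peak Darcy flux magnitude.

With the average cycle 1-3 parameter set these runs reproduce the
qualitative predictions of the calibrated model: stiffness increasing
with rate; full recovery at 2% strain but a residual equilibrium stress
at 10%; a relaxation rate that rises with strain up to 6% and falls
beyond it; creep that grows with load while its rate is largest in the
first 100 s at every load; dilation under tension with negative pore
pressure and an influx of water at about 1 µm/s; and a matrix
contribution of roughly 1% of the total stress.

Two reported predictions are quantitative: moduli "of the order of" 300
and 900 MPa at 0.1 and 1.0 mm/s. Our runs give about 160 and 520 MPa —
the same 3× rate ratio, but smaller absolute values. The discrepancy is
structural rather than numerical: with a 20 N peak (12.3 MPa nominal
stress) the tangent modulus of the exponential fibre law cannot exceed
$\approx k_1\sigma \approx 490$ MPa anywhere on the curve, so a 300 MPa
60-90%-window slope would require a displacement amplitude beyond the
20 N crossing. Those reported values evidently correspond to the
experimental first-peak displacement, which is larger than the calibrated
model's 20 N crossing and is not recoverable from the available record;
we keep the self-contained amplitude definition rather than tune it.

## Calibration

`fit_calibration()` minimises the segment-wise mean squared force error

$$f = \frac16\sum_{i=1}^{6}\frac1{n_i}\sum_{j=1}^{n_i}
      \left((F_{mod})_j - (F_{exp})_j\right)^2$$

over the six monotonic load steps of a three-cycle protocol
(`segment_protocol()` splits at displacement reversals with a hysteresis
guard of 2% of the displacement range). The reported RMS is $\sqrt f$ in
Newtons — the only reading consistent with a mean-squared-force objective.
Optimisation is Nelder-Mead in transformed coordinates: logarithms for the
eight positive parameters and a scaled logit mapping $\nu_m$ onto
(0, 0.499), so every simplex point is an admissible parameter set
(property-tested). The optimiser runs in sweeps of a few hundred
simplex iterations; after each sweep the simplex is rebuilt at the
incumbent (a restart, the automated analogue of manually re-seeding a
simplex search that is known to be init-sensitive), and the fit stops
when a sweep improves the objective by less than $10^{-5}$ N$^2$. We use
`stats::optim`'s Nelder-Mead with its native initial-simplex scaling
(10% per coordinate) rather than re-implementing the simplex to fine-tune
the initial spread; the sweep restarts dominate convergence behaviour in
any case. Forward-model failures at a candidate return a large finite
penalty ($10^{12}$ N$^2$) chosen to exceed any physically reachable
objective value, so the simplex retreats from pathological corners instead
of being attracted to them. An optional multi-start perturbs the starting
point in transformed coordinates.

The forward model for calibration runs the FE solver on a coarse 2×8 mesh
by default — the tensile state is nearly homogeneous, and the patch-test
and mesh-convergence results justify the coarse grid — on the protocol's
own time grid (or a coarsened one).

**Identifiability.** On zero-noise synthetic three-cycle data generated
with the average parameter set, the fit recovers the five fibre
parameters to within a few percent from a starting point with every
positive parameter doubled. The fluid and matrix parameters ($k_0$,
$M_k$, and to a lesser degree $E_m$, $\nu_m$) are only weakly identified
by uniaxial tension — the misfit surface is nearly flat along them — which
is expected: tension barely probes volumetric matrix response, and at
these permeabilities the cycle is far from the consolidation time scale.
The recovery test therefore checks only the fibre parameters, and a
companion probe shows that order-of-magnitude changes in $k_0$ leave the
optimum objective nearly unchanged.

## The synthetic cohort

Because the animal force-displacement records are not deposited, the
package generates specimen-like data with the experiment's structure
(`cohort_spec()`, `generate_cohort()`): nine specimens, displacement
control at 0.1 mm/s reversing at 20 N and 1 N (reversals located by
within-step bisection to $10^{-3}$ N, keeping the peaks sharp), twenty
cycles, mean geometry 8.4 mm / 1.63 mm$^2$. Inter-specimen variability
draws each positive parameter log-normally with the coefficient of
variation of the corresponding specimen-specific fit (e.g. 2.26 for
$E_1$, 1.48 for $E_2$, 0.16 for $k_1$); log-normals are a modelling
choice — the fitted population is only summarised by mean/SD/CV, and
log-normals respect positivity while matching both moments. $\nu_m$ uses
a truncated normal on (0.05, 0.49) and the geometry a truncated normal
with CV 0.1 (the geometric scatter of the animals is not reported; 10% is
typical biological variability for rodent tendon dimensions). Measurement
noise is additive white noise on force with sd 0.1 N, about 0.5% of the
peak — the instrument noise is likewise not reported. A JSON truth ledger
of the generating parameters accompanies every cohort so that
calibration closes the loop.

What the generator deliberately does not emulate: crimp/toe-region
nonlinearity and fibre recruitment (outside the constitutive model),
grip slippage, drift of the force zero, or the failure ramp. Passing the
recovery test therefore demonstrates that the pipeline inverts *this
model's* data faithfully — not that the model captures every feature of
real tendon records.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run the average-tendon
configuration at the package defaults: the 4×16 mesh for the headline
predictions (ramps at 0.1/1.0 mm/s, one 1-20 N cycle, the 2-10%
relaxation sweep), the 1×32 column for consolidation, and the 2×8
forward mesh with a three-cycle, zero-noise synthetic protocol for the
recovery study. These sizes are the package's working defaults; the
mesh-convergence and time-refinement properties above are what justify
them.

## Known limitations

* Tension-dominated protocols leave the fluid/matrix parameter subset
  weakly identified; confined compression or osmotic loading would be
  needed to pin them.
* Under tension the model predicts water influx (negative pore pressure),
  as this model class does on straight cylinders; fluid exudation as seen
  in some experiments would require barrelled geometries, osmotic
  swelling or an orthotropic matrix, all outside scope.
* No fibre dispersion, recruitment, damage or failure; the model is for
  intact tendon under moderate cyclic loads.
* Equal-order u-p elements limit how small the time step can usefully be
  at fine meshes (pressure oscillations); the defaults stay in the stable
  regime.
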