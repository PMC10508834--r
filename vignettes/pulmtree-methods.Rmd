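---
title: "Multiscale pulmonary hemodynamics and polynomial-chaos sensitivity analysis with pulmtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale pulmonary hemodynamics and polynomial-chaos sensitivity analysis with pulmtree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pulmtree` simulates pulse-wave propagation through the proximal pulmonary
arteries and veins, couples them through structured-tree models of the
microvascular beds, and quantifies how uncertainty in eight material and
geometric parameters propagates into pressures, flows, wall shear stress
(WSS), cyclic stretch (CS) and wave-intensity profiles. This vignette is the
package's account of the underlying science: the model and its assumptions,
the numerical choices, the design decisions that were genuinely open, and
what the synthetic study conditions do and do not establish about real data.

# The two model scales

## Proximal 1D model

The 27 proximal vessels (15 arteries to the segmental level, the 4 large
pulmonary veins and their first daughter generation) are cylindrical,
impermeable, thin-walled elastic tubes. With area $A(x,t)$, flow $q(x,t)$ and
transmural pressure $p(x,t)$, mass and momentum balance read

$$\partial_t A + \partial_x q = 0, \qquad
\partial_t q + \frac{\gamma+2}{\gamma+1}\,\partial_x\!\frac{q^2}{A}
 + \frac{A}{\rho}\,\partial_x p = -2\pi\nu(\gamma+2)\,\frac{q}{A},$$

where the power-law velocity profile exponent $\gamma = 9$ gives a blunt
core with a thin viscous boundary layer (the friction factor $\gamma+2 = 11$
also enters the proximal WSS). Blood is Newtonian in the large vessels:
$\rho = 1.055$ g/cm³, $\nu = 3.03\times 10^{-2}$ cm²/s. The wall law

$$p = \tfrac{4}{3} K \left(\sqrt{A/A_0} - 1\right), \qquad K = Eh/r_0,$$

is linearly elastic; all arteries share $K_A$ and all veins $K_V$. Its
linearized pulse-wave speed is $c_0 = \sqrt{2K/(3\rho)}$, about 7 m/s at
$K = 8\times10^5$ g/cm/s² — the package verifies this against the measured
propagation speed of a small pulse to within 1%.

Units are CGS throughout the internals (pressure in g/cm/s² = dyn/cm²);
mmHg appears only at the I/O surface with 1 mmHg = 1333.22 g/cm/s².

## Distal structured trees

Each terminal artery is the root of a self-similar bifurcating tree: the
branch with generation indices $(i,j)$ has radius
$r_{ij} = \alpha^i \beta^j r_{\text{root}}$ and length
$L_{ij} = r_{ij}\,\ell_{rr}$. Branches below the cutoff $r_{\min}$ are not
generated; a branch is terminal when both of its daughters would fall below
the cutoff, and when only the minor ($\beta$) daughter falls below it the
branch continues through the major daughter alone. This reading keeps the
major-daughter pathway depth equal to the brute-force iteration
$r \leftarrow \alpha r$ (the natural meaning of a radius cutoff) while never
producing orphan branches. The venous half of each bed mirrors the arterial
index set with radii rescaled by the venous root radius and lengths from
$\ell_{rr,V}$; arterial terminals join their mirrored venous terminals where
the beds meet at $r_{\min}$. How the original two-sided implementations pair
arterial and venous terminals when the root radii differ is not documented
anywhere we could find; mirroring is the simplest construction consistent
with "the same geometry" on both sides, and it is what the package tests.

Distal flow is viscous-dominated and periodic, so each branch is solved in
the frequency domain. Womersley's oscillatory tube flow gives the profile
factor

$$F(\omega) = 1 - \frac{2 J_1(w_0)}{w_0 J_0(w_0)}, \qquad
w_0^2 = \frac{i^3 r^2 \omega \rho}{\mu},$$

and each branch the symmetric two-port admittance
$Y_{11}=Y_{22}=-ig\cot(\omega L/c)$, $Y_{12}=Y_{21}=ig\csc(\omega L/c)$ with
line admittance $g = \sqrt{C (\pi r^2/\rho) F}$, wall compliance per length
$C = \tfrac{3}{2}\pi r^2 / K_{ST}$ and wave speed $c = g/C$. At $\omega = 0$
this collapses to the Poiseuille conductance matrix
$\tfrac{\pi r^4}{8\mu L}\begin{psmallmatrix}1&-1\\-1&1\end{psmallmatrix}$.
Two numerical points deserve note:

* **The Womersley argument includes the blood density.** Written without
  $\rho$, $w_0$ is not dimensionless when $\mu$ is a dynamic viscosity; the
  package uses the standard form above, under which the zero-frequency limit
  reduces exactly to Poiseuille flow (a tested identity).
* **Resonant frequencies.** $\sin(\omega L/c)$ never vanishes on the grid
  because $c$ is complex for $\omega > 0$, but near-resonances are evaluated
  through scaled complex exponentials (the transfer-matrix-equivalent form),
  which neither overflows nor divides by a vanishing sine.

The Bessel-function ratio $J_1/J_0$ at complex argument is computed by
backward (Miller-type) recurrence on $J_n/J_{n-1}$, started above $1.3|w_0|$;
it matches a high-precision power-series oracle to $10^{-12}$ at moderate
arguments and tends to the flat-profile limit $F \to 1$ at large ones.

**Apparent viscosity.** In microvessels the effective viscosity depends on
calibre. The structured trees default to the Pries-type in-vitro law at
discharge hematocrit 0.45,
$\eta_{\mathrm{rel}}(D) = 220 e^{-1.3D} + 3.2 - 2.44 e^{-0.06 D^{0.645}}$
($D$ in µm), relative to a plasma viscosity of 1 cP. The plasma value was
chosen so the large-vessel limit, 3.2 cP, coincides with the bulk
$\rho\nu = 3.197$ cP to about 0.1%, making the distal and proximal
rheologies consistent. A constant-viscosity mode exists for ablation.

## Grand admittance and memoization

The whole two-sided bed is a two-port between its arterial and venous roots.
Because every branch with the same $(i,j)$ heads an identical subtree, the
composition is computed once per distinct index pair: cascade the arterial
segment, the parallel sum of the daughter bed two-ports, and the venous
segment, eliminating the two interior junction pressures by a closed-form
2×2 solve per frequency. A tree whose literal expansion has millions of
branches costs a few hundred compositions. The package keeps the grand
admittance in the *into-port* convention (both port flows directed into the
bed), under which the matrix is symmetric, satisfies $Y(0)\,[1,1]^T = 0$ (no
flow under uniform pressure) and has a positive-semidefinite real part at
$\omega = 0$ (passivity); the physical vein outflow is the negative of the
second port flow. Correctness is established against an independent oracle:
the literal tree assembled as a sparse nodal admittance system and Schur
complemented onto the two ports agrees with the recursive composition to
better than $10^{-10}$ at every grid frequency.

One empirical property is worth recording because it runs against a naive
expectation: at $\omega = 0$ the bed conductance *increases* with
$r_{\min}$ everywhere in the prior box. The smallest generations dominate
the series resistance of the two-sided path (per-branch conductance scales
as $r^3/\ell_{rr}$ and $\alpha^3 + \beta^3$ is near or below 1 over most of
the prior), so pruning them — on both the arterial and the mirrored venous
side — removes resistance. Conductance is also monotone increasing in
$\alpha$ and $\beta$, consistent with the clinical picture that loss of
small-vessel density raises pulmonary pressures.

## Coupling the scales

The inverse Fourier transform of the grand admittance gives real, T-periodic
kernels $y_{ij}(t)$ sampled on the storage grid; the coupled boundary
condition is the discrete circular convolution

$$q_A(L,t) = (y_{11} * p_A + y_{12} * p_V)(t), \qquad
q_V(0,t) = -(y_{21} * p_A + y_{22} * p_V)(t).$$

The lag-0 kernel coefficient is treated implicitly — at each boundary solve
it couples the new pressures to the new flows — while the remaining history
is summed explicitly from the ring buffer of stored boundary pressures (the
history term is refreshed once per storage interval). The implicit part and
the outgoing characteristic of each vessel form a 2×2 Newton system per bed
and time step, solved to a residual of $10^{-12}$ relative to the
characteristic flow scale. Histories warm-start at zero and the first cycle
is excluded from convergence checks.

# Numerics

* **Scheme.** Two-step Lax–Wendroff on the conservative flux form, with the
  pressure-gradient term integrated exactly via
  $B(A) = f A^{3/2}/(3\rho\sqrt{A_0})$. Empirical order of accuracy on a
  smooth single-vessel pulse is ≥ 1.9 once the characteristic boundary
  closures carry the friction source along the characteristic path
  ($dW_\pm/dt = -2\pi\nu(\gamma+2)u/A$); without that correction the
  boundaries degrade the global order to ~1.2.
* **Boundaries.** Riemann invariants $W_\pm = u \pm 4c$ with
  $c = c_0 (A/A_0)^{1/4}$ have closed form under this wall law. Junctions
  (one parent, two daughters — diverging on the arterial side, converging on
  the venous side) solve flow conservation plus static-pressure continuity
  with the outgoing invariants by damped 3×3 Newton iterations. Static
  rather than total pressure is matched: that is what the coupled junction
  equations state, even though the surrounding prose in the source
  literature says "total pressure"; at pulmonary velocities the dynamic head
  $\tfrac{1}{2}\rho u^2$ is ≲ 1% of the pressure drop, so the distinction is
  below other model errors.
* **Grids.** Per-vessel uniform $\Delta x$ (default ≤ 0.25 cm, at least 8
  interior nodes); the storage/frequency grid has 1024 samples per period by
  default, and the solver sub-steps within each storage interval at a target
  Courant number of 0.5 with a hard abort at 1. Cycle-to-cycle relative
  change of midvessel pressure and flow below $10^{-3}$ defines periodic
  convergence (cap 30 cycles; a non-converged run is returned flagged).
* **Scaled-down study numerics.** The surrogate study uses 256 samples per
  period, $\Delta x \le 0.6$ cm with ≥ 4 interior nodes and Courant target
  0.75, which reproduces the full-resolution MPA systolic pressure to
  within 1% while costing ~1.6 s per simulation; problem sizes for the
  study are 200 training plus 50 validation simulations at polynomial
  degrees 2 and 3.

# Quantities of interest

Proximal WSS uses the power-law profile, $\mu \bar U (\gamma+2)/R$, at the
vessel midpoint. Distal mean WSS is Poiseuille, $4\mu \bar Q/(\pi \bar R^3)$
with the radius-dependent viscosity — the dimensionally consistent form of
the Poiseuille shear stress. Cyclic stretch is
$(\max R - \min R)/\min R$ over one period; distally the radius waveform is
reconstructed through the linearized compliance $A(t) = A_0 + C\,p(t)$,
consistent with the linear distal model (whether the original
implementations linearized here is undocumented; the nonlinear
reconstruction differs by under a percent at distal pressure amplitudes).

Wave-intensity analysis uses centred periodic differences and the local
wall-law wave speed $c(t) = \sqrt{(2K/3\rho)\sqrt{A/A_0}}$ (a frozen
diastolic speed is available, since the classification literature does not
fix the convention), with
$dP_\pm = (dP \pm \rho c\, dU)/2$, $dI_\pm = dP_\pm dU_\pm$, and the
four-type classification by the sign of $dP_\pm$: forward/backward
compression/decompression (the decompression types are also called
expansion waves). Raw per-sample increments are the default; a
$1/\Delta t$-normalized option makes cumulative integrals
resolution-independent.

# The synthetic study conditions

The boundary data driving the published analyses of this model family come
from external sources (an MRI-derived inflow; a lumped-parameter left-heart
model) that are not redistributable, so the package generates synthetic
stand-ins with the physiological structure the analysis relies on:

* **Inflow**: a single-peak raised-cosine ejection pulse, band-limited to 10
  harmonics, zero diastolic baseline, stroke volume 70 cm³ at T = 0.85 s
  (cardiac output 4.9 L/min) — package defaults chosen as typical resting
  adult values, not values from any specific dataset.
* **Left-atrial pressure**: mean 5 mmHg with an a-wave (atrial contraction,
  late cycle) and a v-wave (atrial filling, mid cycle) as band-limited
  von-Mises bumps, producing the x- and y-descents between them.

Band-limiting a waveform with flat segments necessarily leaves ~0.1%
ripple, so "single-peak" and "two local maxima" are asserted above a 2%
prominence floor. Under these conditions the midpoint-parameter model
produces normotensive pulmonary hemodynamics (MPA ≈ 33/9 mmHg, mean
16 mmHg; veins near the 5 mmHg boundary value) and conserves mass through
the full circuit to 0.1%.

What passing under synthetic conditions shows — and what it does not: the
solver, coupling, back-substitution and surrogate machinery are verified
against oracles and invariants that do not depend on the waveform shapes;
the *sensitivity structure* (tree geometry dominating stiffness, $K_V$
owning venous CS) is robust across these conditions; but absolute WSS/CS
magnitudes and wave timings do depend on the inflow amplitude and atrial
waveform, and should not be read as patient-level predictions.

# The surrogate pipeline

Parameters are sampled by Latin hypercube within the prior bounds
(stiffnesses $K_A \in [5.6, 10.4]\times10^5$,
$K_{ST} \in [1.75, 3.25]\times10^5$, $K_V \in [5.95, 11.1]\times10^5$
g/cm/s²; $\alpha \in [0.80, 0.92]$, $\beta \in [0.60, 0.70]$,
$\ell_{rr} \in [10, 50]$ on both sides, $r_{\min} \in [10^{-3}, 10^{-2}]$
cm). Outputs are expanded in tensorized Legendre polynomials of total degree
$\le \mathcal{K}$ ($J = \binom{8+\mathcal{K}}{\mathcal{K}}$ basis functions;
495 at $\mathcal{K} = 4$), fitted by QR-based ordinary least squares — one
shared basis, a coefficient matrix across time points for dynamic outputs.
Closed-form normalization factors give the mean, variance, first-order and
total-order Sobol' indices directly from the coefficients, and the
generalized (cumulative-variance-weighted) indices summarize time series;
all of these are tested against analytic decompositions (additive models,
Ishigami) and a pick-freeze Monte-Carlo estimator.

A statistical caveat the package surfaces honestly: ordinary least squares
needs $n$ comfortably above $J$ (it warns below $2J$). At the desk-scale
study size of 200 training runs, degree 3 ($J = 165$) *overfits* — held-out
MSE rises from degree 2 to degree 3 even though the ranking conclusions are
unchanged — whereas with ample training data the expected monotone
improvement with degree is recovered (demonstrated on smooth test functions
in the unit suite). Degree-4 fits at this budget are not possible at all
($J = 495 > n$). Failed or non-periodic training simulations are excluded,
with a hard 5% cap before the study aborts; under the default conditions
none fail.

# Known limitations

* Straight cylindrical vessels; no curvature, tapering within a vessel,
  gravity, or respiratory variation.
* The wall is purely elastic — no viscoelasticity — and the structured-tree
  stiffness is radius-independent.
* The trees terminate at $r_{\min}$: there is no explicit capillary sheet,
  so "terminal WSS" refers to the smallest arterioles/venules of the tree.
* Junction losses are neglected (pressure continuity, no loss coefficients).
* The distal model is linear; its CS uses the linearized compliance.
* Waveform generators emulate physiological shape classes; they fit no
  recording.
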