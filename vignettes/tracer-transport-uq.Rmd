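---
title: "Stochastic modelling of parenchymal tracer transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic modelling of parenchymal tracer transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphuq)
```

## The model

After intrathecal injection, an MRI contrast agent (gadobutrol) spreads
through the cerebrospinal fluid (CSF) of the subarachnoid space (SAS) and
enters the brain parenchyma. How much of that transport is pure diffusion
and how much is carried by interstitial fluid flow — the glymphatic
hypothesis — is contested, and the governing parameters are uncertain by
factors of several. `glymphuq` treats those parameters as random variables
and random fields, propagates them through a transport simulation, and
reports the resulting uncertainty in clinically interpretable quantities.

The tracer concentration $c(t, x)$ in the parenchymal domain
$\mathcal{D}$ obeys a convection–diffusion–reaction equation in divergence
form,

$$\dot c + \nabla\cdot(v\,c) - \nabla\cdot(D^*\nabla c) + r\,c = 0,$$

with $c = 0$ at $t = 0$, a Dirichlet condition $c = g$ on the SAS
interface and zero diffusive flux on the ventricular interface. $D^*$ is
the effective parenchymal diffusivity of gadobutrol, $v$ a homogenized
interstitial bulk velocity, and $r \ge 0$ a first-order drainage (e.g.
capillary absorption or lymphatic outflow).

Five stochastic coefficient structures are supported:

| model | $D^*$ | $v$ | $r$ |
|-------|-------|-----|-----|
| D1 | random variable | 0 | 0 |
| D2 | random field | 0 | 0 |
| V1 | constant $1.2\times10^{-10}$ | divergence-free glymphatic field | 0 |
| V2 | constant | V1 + deterministic directional field | 0 |
| V3 | constant | radial inflow | $10^{-5}\,\mathrm{s^{-1}}$ |

### The SAS boundary model

The Dirichlet value is $g(t,x) = c_{\mathrm{CSF}}(t)\,h(t,x)$. The spatial
profile

$$h(t,x) = 0.5 + \tfrac1\pi\arctan\!\big(-a\,(x_3 - z_0 - u_{x_3}t)\big)$$

is a smooth step rising along the vertical axis at speed
$u_{x_3} = 1.5\times10^{-5}\,$m/s from $z_0 = -0.2$ m, with steepness
$a = 20\,\mathrm{m^{-1}}$; it models the tracer front climbing from the
spinal to the cranial SAS. $z_0$ is used as an absolute z-coordinate: the
mesh convention puts $z = 0$ at the lateral-ventricle level, which makes
$-0.2$ m a well-defined level below the foramen magnum.

$c_{\mathrm{CSF}}$ is coupled to the simulation through conservation of the
injected amount $n_0 = 0.5$ mmol in a CSF volume
$V_{\mathrm{CSF}} = 140$ mL: at any time, what is neither in the parenchyma
nor drained resides in the CSF, so

$$c_{\mathrm{CSF}}(t) = \Big(n_0 - \int_\mathcal{D} c\,\mathrm{d}x -
\int_0^t\!\!\int_\mathcal{D} r\,c\,\mathrm{d}x\,\mathrm{d}\tau\Big) / V_{\mathrm{CSF}},$$

giving $c_{\mathrm{CSF}}(0) = 3.57$ mol/m³ and a boundary value that falls
as the brain takes tracer up. When the convective ventricular boundary term
is active (velocity models), the amount advected through the ventricular
wall is tracked as an additional budget component and treated as removed
from circulation, so the closure identity remains exact for every model.

### Stochastic coefficients

**D1.** $D^*(\omega) = 0.25\,D^*_{\mathrm{Gad}} + \Gamma(k{=}3,\,
\theta{=}0.75\,D^*_{\mathrm{Gad}}/3)$ with
$D^*_{\mathrm{Gad}} = 1.2\times10^{-10}\,$m²/s. The offset guarantees
positivity; the expectation equals $D^*_{\mathrm{Gad}}$ and values 2–3
times larger or smaller occur with low probability.

**D2.** The same marginal at every point of a spatially correlated field
with correlation length 0.01 m. Construction: a standard Matérn Gaussian
field is mapped through the normal CDF and the gamma quantile function
(Gaussian copula). The pointwise marginal is then exact; the induced
spatial correlation is only approximately Matérn — a deliberate
approximation, stated here once. Because trilinear interpolation of a
unit-variance grid field loses variance between grid nodes, interpolated
values are renormalized by their exact interpolation standard deviation
before the copula transform, so the marginal is exact at every mesh vertex.

**Matérn convention.** Smoothness is $\nu = 1/2$ (exponential covariance)
by default, and the correlation length $\lambda$ is the distance at which
correlation decays to $e^{-1}$; both are configurable in `matern_spec()`.
Fields are sampled on a regular auxiliary box grid by circulant embedding
(FFT), padded so that points are separated by at least $6\lambda$ around
the torus; residual negative embedding eigenvalues (a fraction of a
permille for the exponential family) are clipped. The sampler warns when
the grid spacing exceeds $\lambda/3$, but permits it: brain-scale sampling
of the 1020 µm velocity fields on a practical grid is necessarily
under-resolved, and the scaling constant is calibrated through the same
pipeline, so the target RMS still holds for the fields as used.

**V1.** $v = v_{\mathrm{avg}}\,\eta\,10^{-\mathcal{E}(\omega)}\,
\nabla\times\psi(\cdot,\omega)$, where $\psi$ has three i.i.d. standard
Matérn components with $\lambda = 1020$ µm (the arteriole–venule spacing),
and $\mathcal{E}\sim\mathrm{Exp}(\text{mean } 0.2)$ is drawn once per
realization. The curl makes every realization divergence-free; centered
finite differences are used on the grid, whose discrete divergence vanishes
identically because centered difference operators commute. The constant
$\eta$ is calibrated so that $\mathbb{E}[\|v\|^2]^{1/2} =
v_{\mathrm{avg}} = 0.17$ µm/s; with the $v_{\mathrm{avg}}$ prefactor
already in the definition, $\eta =
(\mathbb{E}[10^{-2\mathcal{E}}]\,\mathbb{E}[\|\nabla\times\psi\|^2])^{-1/2}$,
where the attenuation moment is evaluated in closed form
($5/(5 + 2\ln 10) \approx 0.5206$) and the curl second moment by a seeded
Monte Carlo run through the full sampling/interpolation pipeline at the
points where the field will be evaluated.

**V2.** A V1 realization plus the deterministic directional field

$$v_{\mathrm{dir}}(x) = -v_f\big(\arctan(15x_1)(|x_1|-0.1),\;
\arctan(15x_2)(|x_2|-0.1),\; -0.9x_3 + 0.06 - \sqrt{x_1^2+x_2^2}\big),$$

$v_f = 2\times10^{-6}$ m/s, mimicking cardiac-pulse-driven flow up the
brain stem that spreads and slows. The formula is evaluated exactly as
printed; note that on the brain-stem axis below $x_3 = 0.06/0.9$ its
vertical component is positive (upward), and the field induces a small net
outflow through the boundary.

**V3.** $v = \bar v(\omega)\exp\!\big({-3(R-\rho)^2}/({R^2-(R-\rho)^2})\big)
(x_c - x)$ with $\rho = \|x - x_c\|$, $R = 0.08$ m and $x_c$ the
ventricular center: radially inward flow vanishing at the center. At
$\rho = 0$ the limit 0 is used and the field is zero beyond $2R$, where the
printed expression is undefined. $\bar v \sim \Gamma(k{=}2, \theta)$ with
$\theta$ set from mesh quadrature of the squared spatial profile and
$\mathbb{E}[\bar v^2] = k(k+1)\theta^2$ so that the RMS magnitude again
equals $v_{\mathrm{avg}}$. Drainage $r = 10^{-5}\,\mathrm{s^{-1}}$ removes
the net inflow's tracer load.

## Numerics

Space is discretized with continuous piecewise-linear (P1) finite elements
with mass lumping; time with the implicit midpoint rule, $\Delta t =
15$ min by default. Convection is assembled in the divergence form of the
equation with cell-averaged velocities; the convective boundary term from
integration by parts is retained on the ventricle facets (the natural
weak-form reading of the zero-diffusive-flux condition) and is
configurable. Dirichlet conditions are enforced by row replacement on all
SAS nodes, including nodes shared with ventricle facets. Because the
coefficients of one realization are constant in time, the system matrix is
factorized once (sparse LU) and reused for all steps; the factorization
tolerance is part of the problem record, and identical problems reproduce
bitwise.

The boundary coupling is explicit and trapezoidal: the Dirichlet value over
$[t_n, t_{n+1}]$ is $c_{\mathrm{CSF}}(t_n)\,(h(t_n) + h(t_{n+1}))/2$, and
$c_{\mathrm{CSF}}$ is recovered after the step from the conservation
identity. Two consequences are worth stating plainly:

* the *budget closure residual* — parenchymal + SAS + drained (+
  ventricular) against $n_0$ — is zero to machine precision by
  construction, except when the SAS empties and the floor at zero engages;
  the residual trace reported per step measures exactly those events;
* the genuinely first-order-in-$\Delta t$ error of the coupling is the
  *lag* between the stale $c_{\mathrm{CSF}}$ used during a step and the
  consistent end-of-step value. The solver reports it per step
  (`coupling_lag`, in units of $n_0$), and halving $\Delta t$ halves it.
  The initial step is excluded from refinement comparisons: $c(0) = 0$ is
  incompatible with $g(0) > 0$, so the first step performs a
  $\Delta t$-independent boundary-layer fill.

The scheme is second-order in space (verified against separable analytic
diffusion solutions) and first-order in time overall. No stabilization is
used by default: the transport is only mildly convection-dominated, with a
Péclet estimate $9 L v_{\mathrm{avg}} / D^*_{\mathrm{Gad}} \approx 1071$
for $L = 0.084$ m.

Concentrations may undershoot zero by a small discretization tolerance near
steep fronts; the minimum over the run is reported
(`min_concentration`) rather than clipped.

## The synthetic geometry

`build_synthetic_brain()` is a deliberate idealization, not an anatomical
reconstruction: a gray-matter ellipsoidal shell (default semi-axes 0.07,
0.09, 0.08 m; thickness 0.02 m) around a white core, with a central
spherical ventricular cavity (radius 0.02 m) whose surface carries the
ventricle label while the outer surface carries the SAS label. It preserves
exactly the features the transport model uses — two compartments, two
boundary types, and the z-stratified SAS exposure with $z = 0$ at the
cavity center — at desk scale. Directions come from a subdivided
octahedron; radial layers interpolate between the cavity sphere and the
bounding ellipsoids, so the mesh is conforming by construction and its
volume converges to the analytic ellipsoid-minus-sphere value.

Radial layers in the gray shell are graded geometrically toward the SAS
surface (outermost layer 2 mm by default, growth ratio 1.5). This mirrors
the near-surface refinement of atlas FEM meshes, and it is load-bearing:
the explicit SAS coupling is stable only while the tracer-holding capacity
of the first cell layer (surface area × first-layer thickness ×
concentration) stays well below $V_{\mathrm{CSF}}$. With a 2 mm outer
layer on the default geometry that ratio is about 0.3; with 10 mm layers
the coupled system oscillates, which is a property of the
discretization, not of the model.

Default subregions of interest are 4 mm spheres: $S_g$ centered 3 mm
beneath the SAS surface on the positive x-axis at $z = 0$, and $S_w$
mid-way through the white core on the same axis. The source geometry only
depicts these regions graphically, so the defaults are explicit stand-ins
and fully configurable; on meshes too coarse to resolve a 4 mm sphere the
radius is grown geometrically until at least one cell centroid falls
inside.

What the idealization does *not* emulate: cortical folding. On a folded
brain, white matter lies within a few millimetres of CSF in the sulci; on
the smooth ellipsoid it starts 2 cm deep. Pure-diffusion runs on the
synthetic geometry therefore reach the white matter much more slowly than
on an atlas mesh, and white-matter activation times are routinely censored
at 24 h for models D1/D2. Tests exercise activation-time logic with
convective models and constructed trajectories; passing them demonstrates
the correctness of the machinery, not the anatomical realism of
white-matter delivery. Real labeled atlas meshes can be supplied through
`load_labeled_mesh()` (Gmsh MSH ASCII, VTU, or XDMF with inline data).

## Monte Carlo layer

Per-sample seeds are deterministic hashes of the base seed and the
realization index, so runs are bit-reproducible and samples are
independent of execution order. Summaries per quantity of interest:
sample mean with standard error $(\hat V/N)^{1/2}$, 99.73% empirical
prediction intervals (0.135% of samples in each tail, the $\pm3\sigma$
analogue), Freedman–Diaconis histograms with Scott-bandwidth kernel
densities, and the sample-size criterion $3(\hat V/N)^{1/2} <
0.01\,\hat Q$, reported as a diagnostic rather than enforced — the
criterion is designed for thousands of samples, while desk-scale runs use
$N$ in the tens. Censored activation times are excluded from means and
intervals and reported through the CDF, which saturates at the uncensored
fraction.

## Problem sizes

The package's own verification runs use: the default synthetic geometry
(about 10,000 vertices) for 24 h budget runs; a coarse variant (about
1,500 vertices) for trajectory-refinement studies; and a $10\lambda$
sampling box with a few hundred realizations for velocity calibration
(standard error of the validated RMS near 1%). These sizes were chosen so
each check isolates one property at the accuracy that property needs;
production studies on atlas meshes simply pass a finer mesh and larger
$N$ to the same functions.

## Known limitations

* The SAS is a single well-mixed compartment with a prescribed spatial
  profile; no flow is solved in the SAS, and efflux routes out of the SAS
  itself (arachnoid granulations, dural/nasal lymphatics) are ignored.
* Diffusivity is isotropic; anisotropy and gray/white differences in
  velocity or diffusivity are not modelled.
* The D2 field's spatial correlation is approximate (copula construction).
* The divergence-form convection with row-replaced Dirichlet rows carries a
  first-order boundary-flux consistency error; on coarse meshes with
  strong inflow (V3) this appears as a budget residual of a percent or
  two, vanishing under surface refinement.
* MRI signal intensity is not modelled; comparisons with imaging are in
  terms of tracer amount and timing only.
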