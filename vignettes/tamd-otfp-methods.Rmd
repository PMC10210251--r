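---
title: "Free energy surfaces by temperature-accelerated dynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free energy surfaces by temperature-accelerated dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamdotfp)
```

## The problem

Ion permeation through a voltage-gated sodium channel's
conductivity/selectivity filter (C/SF) is governed by a free energy surface
(FES) over a few collective variables (CVs): the axial position of one or
two Na⁺ ions along the pore, and the axial position of the tip of the
signature-ring side chain (the DEKA lysine ammonium nitrogen, or the
glutamate carboxyl carbon in charge-altering variants). Barriers of several
kcal/mol separate the metastable ion binding sites, so plain molecular
dynamics at 310 K essentially never crosses them on accessible time scales.
This package implements the enhanced-sampling machinery used to map such
surfaces — temperature-accelerated molecular dynamics (TAMD) with on-the-fly
free energy parametrization (OTFP), the accompanying restraint potentials,
string-method extraction of minimum free energy paths (MFEPs), and the
occupancy/geometry analyses — and validates every stage on synthetic model
systems whose free energies are known exactly or by deterministic
quadrature.

Units throughout: kcal/mol, Å, ps, amu, K; `kB_kcal` = 0.0019872041
kcal/(mol·K).

## Model and estimator

For a system with potential $V(x)$ at inverse temperature $\beta$, the free
energy over CVs $\theta(x)$ is
$G(z) = -\beta^{-1}\ln \int e^{-\beta V(x)}\,\delta(\theta(x)-z)\,dx$.
TAMD extends the system with auxiliary variables $z$ tethered to the CVs,

$$U_\kappa(x, z) = V(x) + \frac{\kappa}{2}\sum_j (\theta_j(x) - z_j)^2 ,$$

evolves $x$ by Langevin dynamics at $\beta$ under $U_\kappa$, and evolves
each $z_j$ by overdamped dynamics at an artificial inverse temperature
$\bar\beta < \beta$:
$\bar\gamma \dot z_j = \kappa(\theta_j - z_j) + \sqrt{2\bar\gamma/\bar\beta}\,\eta_j$.
When $\kappa$ is large (tight tether) and $\bar\gamma$ large ($z$ slow),
the instantaneous spring force $\kappa(\theta(x_t) - z_t)$ averages, at
fixed $z$, to $-\nabla G(z)$, while the high auxiliary temperature lets $z$
cross barriers that are prohibitive at $\beta$.

OTFP turns the force samples into a surface estimate. $G$ is expanded in
piecewise-linear chapeau (hat) bases $\phi_m$, and the coefficients solve
the gradient-matching least squares problem
$E(\lambda) = \tfrac12\langle |\nabla G_\lambda(z_t) + f_t|^2\rangle$
with $f_t = \kappa(\theta(x_t) - z_t)$, i.e. the normal equations
$A\lambda = b$ with $A_{mn} = \langle \nabla\phi_m\cdot\nabla\phi_n\rangle$
and $b_m = -\langle \nabla\phi_m \cdot f_t\rangle$. In 1D the elements are
intervals; in 2D each grid cell is split along its lower-left diagonal into
two triangles, so every basis gradient is constant per element and the
assembly is exact without quadrature: only per-element sample counts and
force sums are accumulated. The sign convention is pinned by the property
that the conditional mean of $f$ at fixed $z$ estimates $-\nabla G$, which
the test suite verifies on a coupled harmonic system, where everything is
closed-form: tethering a harmonic coordinate of stiffness $k$ gives an
effective FES $\tfrac12 k_{\rm eff} z^2$ with
$k_{\rm eff} = k\kappa/(k+\kappa)$.

Nodes are *defined* only where the sampling supports them (per-node sample
support ≥ 10 by default); the rest are masked, mirroring the undefined
regions of sampled surfaces. The restricted system has the usual gauge
freedom (an additive constant per connected sampled component); it is fixed
by a tiny ridge ($10^{-9}$ of the mean diagonal) followed by a min-shift of
the defined values to zero. Replica surfaces on the same grid are averaged
pointwise over the intersection of their defined masks — a point enters the
average only where every replica has a value — and re-min-shifted;
averaging is idempotent and gauge-invariant.

## Synthetic study systems

The generators define the study conditions; their defaults are fixed and
are not adjusted per experiment.

* `make_harmonic()` — independent harmonic coordinates; identity-CV free
  energy is the potential itself. Oracle for the $k_{\rm eff}$ law, the
  equipartition and Boltzmann-density checks.
* `make_double_well(height = 6, half_separation = 2, transverse_stiffness
  = 1)` — $V = h((x/a)^2-1)^2 + k_y y^2/2$; barrier 6 kcal/mol ≈ 10 k_BT at
  310 K, in the 2–10 kcal/mol range of the filter's metastable basins. The
  transverse coordinate integrates out exactly, so the marginal along x is
  the x-term up to a constant at any temperature.
* `make_benchmark_surface()` — the Müller–Brown four-Gaussian surface with
  its standard published constants (echoed by `write_potential_config()`),
  the conventional validation ground for string methods: three minima, two
  saddles.
* `make_toy_filter()` — one or two "ions" in a cylinder of radius 7 Å
  (half-harmonic radial wall), Gaussian attractive wells at z = 5 and 12 Å
  (depth 4 kcal/mol, width 1 Å) standing in for the filter binding sites,
  soft container walls at the z-domain edges (default domain [−2, 22] Å,
  matching the extended histogram range, with wells inside the [3, 18] Å
  sampling interval), axial Gaussian pair repulsion, and a 1D "gate"
  particle — a surrogate for the charged side-chain tip — with its own
  double well (centers 6 and 10 Å, barrier 3 kcal/mol) repelling the ions
  through a Gaussian coupling (4 kcal/mol, width 1.5 Å). The joint
  (ion z, gate z) FES has several basins, emulating the coupled
  ion/side-chain rearrangements of the real filter. Pair repulsion acts on
  the axial separation only, which is what matters in a narrow cylinder
  and keeps the transverse coordinates exactly separable.

Separability is what makes the oracles exact: `marginal_fe_oracle()`
computes $G$ by deterministic trapezoid quadrature over the orthogonal
complement of the (linear) CV within the axial subspace, refusing more
than three non-CV dimensions, and reports its own convergence under grid
doubling (warning above $10^{-3}$ kcal/mol). Confinement walls can be
included in the oracle so that it matches a restrained simulation exactly.

What the toy systems do *not* emulate: explicit solvent and counterions,
protein flexibility beyond the single gate coordinate, multi-ion
knock-on with more than two ions, and the atomistic force field. Passing
tests therefore demonstrate the correctness of the estimators and
restraints, not the biology of any real channel.

## Dynamics and numerical choices

* **Integrator.** BAOAB splitting with exact Ornstein–Uhlenbeck velocity
  noise; at zero friction and temperature it reduces to velocity Verlet.
  Accelerations convert with 1 kcal/mol = 418.4 amu·Å²/ps². Default
  timestep 2 fs with particle mass 40 amu, keeping $\omega\,\Delta t
  \lesssim 0.25$ for the stiffest mode (the κ = 1500 kcal/mol/Å² tether).
* **Auxiliary step.** Euler–Maruyama, sharing the physical timestep. This
  requires $\kappa\,\Delta t/\bar\gamma \ll 1$; with the channel defaults
  (1500, 800) the ratio is 0.004. Runs abort with a diagnostic if the
  tether extension diverges or the energy overflows $10^8$ kcal/mol.
* **Thermostat friction and adiabatic separation.** TAMD assumes $x$
  re-equilibrates conditioned on the slowly moving $z$. A quantitative
  criterion: the auxiliary diffuses $\bar D\,\tau_x$ per physical
  relaxation time $\tau_x$, and this must stay well below the tether width
  $k_BT/\kappa$. A weak thermostat (1 ps⁻¹, appropriate for a fully
  atomistic bath) leaves the surrogate's conditional distribution lagging
  and biases the mean force wherever the surface is anharmonic; a very
  strong or overdamped thermostat slows the oscillatory self-averaging of
  the spring force and inflates the estimator variance. The package
  defaults to γ = 10 ps⁻¹ for TAMD runs, the flat region of this
  bias–variance tradeoff for the surrogate systems.
* **Restraints.** The flat-bottom exclusion bias adds, per excluded
  particle, $k\,S(x)S(y)S(z)$ with $S$ a C¹ smoothstep plateau: 1 in the
  box inset by `ramp_width` (default 1 Å), 0 outside, cubic ramp between.
  The displayed functional form of the original bias is not recoverable
  from the source, so this reconstruction is pinned instead to its stated
  properties: the stated box constants, the plateau height k = 600
  kcal/mol, continuity of forces, and the "prohibitive barrier" behaviour
  (excluded particles never enter in 10⁶ steps at 310 K). Half-harmonic
  walls are interpreted with κ in kcal/mol/Å² (dimensional consistency of
  a quadratic penalty); the channel values are 300 at z > 17 / z < 4 Å
  (TAMD confinement) and 100 at z > 25 / z < −2 Å. Walls are applied to
  the physical particles defining the CVs, not to the auxiliaries, which
  then stay in range by tethering; z(0) = θ(x(0)) so the tether starts
  relaxed.

## String method

The MFEP is extracted from a gridded FES by the zero-temperature string
method: steepest-descent displacement of every point by
$-\,\mathrm{step}\cdot\nabla G$ (bilinear value interpolation; gradients
are central finite differences of node values carried through the same
interpolant, exact for linear fields), followed by equal-arclength
reparametrization, until the mean displacement between consecutive
parametrized strings falls below the tolerance (default $10^{-7}$ Å).
Endpoints evolve freely and slide into the basin minima. The step halves
after five consecutive iterations of rising mean energy. Initial strings
are unions of linear interpolations with shared junctions kept once, e.g.
the two-segment construction (5.0, 11.4)→(3, 10) in 8 points plus
(3.0, 10.0)→(15.0, 7.8) in 50 points, giving 57 points.

The validation oracle is exhaustive: minima by dense grid search
(`fes_minima`), and the saddle by the minimax principle (`fes_saddle`) —
grid nodes activated in order of increasing value with union-find
connectivity; the node whose activation first connects the two basins is
the saddle of the best path. On the benchmark surface gridded at 0.05
units the converged string passes within one cell diagonal of the oracle
saddle and the profile maximum matches the saddle height within the spread
of the saddle cell's corner values (the one-cell interpolation error).

## Channel analyses

Occupancy is counted in a cylinder (default radius 7 Å) with inclusive
boundaries on radius and both z bounds (the boundary convention is not
dictated by the analyses being mirrored, so the inclusive choice is fixed
and documented). Bounds come either explicitly or from reference atoms of
a parsed structure (the Cα above the filter; the Cα below, shifted −4 Å).
Occupancy tables report percentages at occupancy 0–4 (higher counts pool
into the top bin with a message), the mean, and the population standard
deviation (the sample value is also returned). Conditional z-histograms
support frame predicates (e.g. single-occupancy frames), pooling across
runs with provenance, the default [3, 18] Å and extended [−2, 22] Å
ranges, the two-ion COM variant, and raw-count or density normalization
(raw by default).

Structures parse through `bio3d`; the first model is kept, alternate
locations resolve to the highest occupancy, insertion codes survive in the
addressing, and an unspecified chain defaults to the one with most
residues (reported). Cross distances d1A–d4B between the outer charged
ring and the signature ring are provided as presets in the channel's
residue numbering; superposition RMSD uses the Kabsch SVD rotation with
reflection correction and is cross-checked in the tests against an
independent numerical optimizer and against `bio3d::fit.xyz`.

## Problem sizes and what the validation shows

The shipped validation runs use 10⁵–2×10⁶ integrator steps per experiment
and 0.25 Å chapeau grids; at these sizes the harmonic recovery lands
within ~0.1 kcal/mol of the closed form, the double-well barrier within a
few percent of 6 kcal/mol, and TAMD at 6000 K crosses that barrier
hundreds of times while plain 310 K dynamics does not cross at all. Two
limitations are worth stating plainly. First, the spring-force samples
carry irreducible thermal noise of magnitude $\sqrt{\kappa k_B T}\approx
27$ kcal/mol/Å; reconstructed 2D surfaces therefore converge like the
square root of the per-cell sample count, and a 61×49-node surface still
has node-level RMS errors of order 1 kcal/mol after 2×10⁶ samples —
faithful use at that size means reading basins and barriers, not
node-level values; replica averaging reduces the error roughly as
$1/\sqrt{K}$. Second, grid cells straddling the steep confinement-wall
flanks (where G changes by tens of kcal/mol across one cell) are sampled
only at their low edge and are not representable by a piecewise-linear
basis; values there are flagged defined only once they reach the support
threshold, but should be treated as qualitative.
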