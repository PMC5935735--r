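---
title: "Continuum electrostatics, pKa shifts and proton-transfer paths with protonpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum electrostatics, pKa shifts and proton-transfer paths with protonpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonpath)
```

# The problem this package addresses

Enzyme mechanisms that shuttle protons — for example a cyclodipeptide
synthase whose catalytic serine ester must be protonated while the
substrate's amino group is deprotonated — hinge on two questions that are
awkward to answer experimentally:

1. **Which protonation state does each titratable group adopt inside the
   protein?** A group's pKa can shift by many units when it is buried in a
   hydrophobic pocket.
2. **Which of several proton-transfer channels does the reaction take?**
   A direct transfer and a relay-assisted transfer can share reactants and
   products yet differ in barrier by an order of magnitude.

`protonpath` implements the desk-scale free-energy machinery for both
questions: a finite-difference linearized Poisson–Boltzmann (LPB) solver
feeding a linear-response estimate of protonation free energies and pKa
shifts, and a chain-of-states minimum-energy-path optimizer with
climbing-image refinement, plus one-sided free-energy perturbation along a
fixed path and a rigid-rotor/harmonic-oscillator vibrational correction.
Every stage is exercised on synthetic systems with known exact answers.

# Continuum electrostatics

## Model

The solute (protein plus substrate) is a single dielectric medium with
`eps_in = 2`; solvent is `eps_out = 80` with monovalent ions at 0.15 mol/L.
The dielectric boundary is the molecular (solvent-excluded) surface traced by
a 1.4 Å probe. The LPB equation

$$\nabla\cdot\big[\varepsilon(\mathbf r)\nabla\phi(\mathbf r)\big]
  - \bar\kappa^2(\mathbf r)\,\phi(\mathbf r) = -4\pi C \rho(\mathbf r),
  \qquad C = 332.0636\ \mathrm{kcal\,\mathring A\,mol^{-1}e^{-2}},$$

is discretized on a regular grid (default spacing 0.4 Å) with charges spread
by trilinear weighting and Dirichlet boundary values from the
Debye–Hückel/Coulombic sum over all charges. Units are fixed globally
(Å, e, kcal/mol); there is deliberately no unit configuration.

## Numerical choices

* **Surface on the grid.** Atom spheres are inflated by the probe radius and
  then eroded by it, which keeps probe-inaccessible re-entrant necks inside
  the solute. Erosion centres are projected onto the inflated surface rather
  than kept on lattice nodes; with node-centred erosion the boundary drifts
  outward by O(h) and the Born benchmark below stops converging.
* **Edge dielectrics.** Each grid edge takes the harmonic mean of the two
  media weighted by the fraction of the edge inside the solute, computed by
  exact segment/sphere intersection (midpoint fallback where the crossing is
  purely re-entrant). The unweighted two-node harmonic mean leaves a ~3%
  Born error at 0.4 Å; the fractional version is the standard
  flux-conserving refinement and reduces it to well under 1%.
* **Screening.** $\bar\kappa^2 = 8\pi C I' / (RT)$ with $I'$ the ionic
  strength as a number density; a Stern ion-exclusion layer of 2 Å (config)
  zeroes it around the solute. At 0.15 M and 300 K the Debye length is
  7.95 Å.
* **Solver.** Red–black successive over-relaxation with
  $\omega = 2/(1+\sin(\pi/n_{\max}))$, converged when the largest
  Gauss–Seidel displacement falls below `tol` (default
  $10^{-6}$ kcal/(mol·e)). Single-level grid, no focusing; the automatic
  grid pads the solute bounding box by max(30 %, 10 Å) per side.
* **Reaction-field energies** are differences of two solves on the identical
  grid (solvated minus uniform `eps_in` reference), so the grid self-energy
  of the spread charges cancels exactly. The Born ion (q = 1 e, a = 2 Å)
  reproduces the closed form $-C q^2(1/2 - 1/80)/2a = -40.47$ kcal/mol to
  0.04 % at 0.4 Å spacing, with monotone improvement over 0.8 → 0.4 Å.

```{r born}
ion <- born_ion(q = 1, radius = 2)
c(computed = reaction_field_energy(ion, spacing = 0.6, ionic_strength = 0),
  exact = born_energy(1, 2))
```

# Protonation free energies and pKa shifts

A titratable site is a set of atoms with per-atom charge differences
$\delta q_i$ (protonated minus deprotonated, summing to +1 e) and a
model-compound pKa. Under linear response, the free energy of the charging
step is

$$\Delta G = \sum_i \delta q_i\,
  \frac{\langle V_i\rangle_A + \langle V_i\rangle_B}{2},$$

with $\langle V_i\rangle$ the electrostatic potential on atom $i$ averaged
over snapshot ensembles of the two endpoint states. This two-ensemble
average is *exact* when the potential fluctuations are Gaussian with equal
variance in both states — precisely what the packaged generator
`make_linear_response_ensemble()` produces, which is why it serves as a
sharp correctness oracle rather than a mere smoke test. The in-protein pKa
follows from the shift

$$\mathrm{p}K_a^{\mathrm{prot}} - \mathrm{p}K_a^{\mathrm{solv}}
  = \frac{\Delta G^{\mathrm{prot}} - \Delta G^{\mathrm{solv}}}{2.303\,RT}.$$

Only the protein-minus-solvent difference is physical: the self-interaction
of the spread site charges is identical in the two runs and cancels.

```{r pka}
# deprotonation 8.9 kcal/mol costlier than the solvent model compound (pKa 4.4)
pka_in_protein(dG_prot = 8.9, dG_solv = 0, pka_solv = 4.4, thermo_config(300))
```

Conventions worth stating:

* $\delta q$ is protonated-minus-deprotonated; the expression is symmetric
  in the ensembles, so only this sign convention matters for the direction
  of the reported $\Delta G$.
* Default temperature 300 K (`thermo_config()`), gas constant
  $1.9872\times10^{-3}$ kcal/(mol K).
* Uncertainties come from 5-block averaging over snapshots.
* Combining a relative $\Delta\Delta G$ with a model pKa at a reference pH
  uses $\Delta G_{\mathrm{abs}} = \Delta\Delta G + 2.303\,RT\,
  (\mathrm{p}K_a^{\mathrm{model}} - \mathrm{pH})$
  (`absolute_protonation_dg()`). This is this package's documented
  convention; other codes use others, so absolute values should only be
  compared within one convention.
* `rank_protonation_states()` re-references to the most stable state and
  breaks exact ties lexicographically.

# Minimum-energy paths and saddle points

Reaction channels are compared on pluggable `energy_surface` objects. The
optimizer is a chain of states (default **20 images**, endpoints fixed):
nudged-elastic-band force projection with energy-weighted upwind tangents
and a spring force along the tangent, alternated with equal-arc-length
string reparameterization every 10 iterations, driven by the FIRE
optimizer. FIRE velocities survive the reparameterization — zeroing them
after every remap strands the optimizer in its small-step regime (measured:
no convergence in $2\times10^4$ iterations on the Müller–Brown surface
versus ~190 iterations when kept). Convergence is declared when the RMS
perpendicular true force over interior images drops below `force_tol`
(default $10^{-4}$).

After the band converges, the highest interior image climbs: its force is
$-\nabla E + 2(\nabla E\cdot\hat\tau)\hat\tau$ with $\hat\tau$ the fixed
neighbour-difference tangent. At the fixed point this force vanishes only
where $\nabla E = 0$, so a converged climbing image (default tolerance
$10^{-6}$ on the gradient norm) is a genuine stationary point; tests verify
exactly one negative Hessian eigenvalue.

Validation uses three packaged surfaces:

* `double_well_1d()` — barrier exactly 1 at $x = 0$;
* `muller_brown()` — the standard four-term exponential benchmark. The
  refined saddle energy is checked against `grid_minimax_saddle()`, a
  brute-force oracle that finds the lowest level at which the two basins
  become 4-connected on a $2000\times2000$ evaluation grid (union-find over
  cells sorted by energy) — independent of all chain-of-states machinery;
* `proton_transfer_surfaces()` — a paired direct/relay construction (below).

```{r dw}
dw <- double_well_1d()
path <- optimize_path(dw, init_path(-1, 1, n_images = 20))
climbing_image_refine(dw, path)
```

# The direct-versus-relay construction

The mechanistic claim being exercised is an *ordering*: a proton transfer
routed through a relay group crosses a much lower barrier than the direct
transfer, with identical reactants and products. Two 2-D surfaces in a
transfer coordinate $x$ and a relay coordinate $y$ capture exactly that:

$$E_{\mathrm{direct}} = D\,(1-x^2)^2 + k y^2, \qquad
  E_{\mathrm{relay}} = (1-x^2)^2\big[D - (D-R_b)
  e^{-(y-y_r)^2/2w^2}\big] + k y^2 .$$

Both share minima at $(\pm1, 0)$ with energy 0 (so equal reaction energies,
and the endpoint gradients vanish identically); the relay surface opens a
channel near $y_r$ where the ridge drops from $D$ to about $R_b + k y_r^2$.
Defaults $D = 5$, $R_b = 1$, $k = 0.5$, $y_r = 1$, $w = 0.35$ were chosen
once so that the two channels differ by well over a factor of two — the
deliberately modest, dimensionless analogue of a ~60 vs ~12 kcal/mol
separation — and are not tuned thereafter; the full pipeline reports the
ratio, not the absolute numbers, as the scientific output. The surfaces are
2-D by design: the ordering claim is about which channel the path takes,
which a two-coordinate model exercises fully at desk scale.

# Free-energy perturbation along a fixed path

With the reactive region frozen at each image's optimized geometry and only
the environment sampled, the free-energy change between adjacent images is
the one-sided exponential (Zwanzig) average

$$\Delta A^{i\to i+1} = -\frac{1}{\beta}
  \ln\big\langle e^{-\beta\,\Delta E_{\mathrm{pert}}^{i\to i+1}}
  \big\rangle_{i},$$

computed in the log domain (shift by the maximum) so arbitrarily large
perturbation energies never overflow. Only the one-sided form is
implemented — no bridge or multistate reweighting estimators — and standard
errors come from 5-block averaging. Jensen's inequality
($\Delta A \le \langle\Delta E\rangle$) holds exactly for the estimator and
is asserted property-style. On a Gaussian bath the estimator has a closed
form ($\mu - \beta\sigma^2/2$), giving exact targets for the tests; a
Boltzmann-consistent bath additionally verifies that the cumulative profile
is a state function (reversal negates it, increments telescope). Default
ensemble size is $10^3$ configurations per image, scaled for desk-top
runtimes; the tests state the sizes they use.

The vibrational correction `rrho_vibrational_free_energy()` performs
mass-weighted normal-mode analysis of a Hessian in kcal/mol/Å² with masses
in amu and returns $\sum_k [\hbar\omega_k/2 + k_BT\ln(1-e^{-\hbar\omega_k
/k_BT})]$; negative-curvature modes are counted and excluded, as are
near-zero (rigid-body) modes below `zero_tol`.

# What the synthetic generators do and do not emulate

The generators supply every fixture the pipeline needs — Born ions, a ≤30
atom two-site active site (four protonation states with net charges
0/+1/+1/+2), equal-variance Gaussian potential ensembles with recorded
exact free energies, and the benchmark surfaces. They are pure functions of
their seed (bitwise reproducible, session RNG untouched). They deliberately
do **not** emulate: force-field realism or hydrogen placement, conformational
reorganisation coupled to protonation (snapshot ensembles here are i.i.d.
jitters, not correlated trajectories), unequal-variance (non-linear-response)
electrostatics, or Cartesian molecular reaction paths. Passing tests
therefore certify the estimators and solvers against their defining
mathematics, not the fidelity of any particular protein model.

# Known limitations

* Linearized PB only; no nonlinear term, no multigrid focusing, and a
  single dielectric value for the whole solute.
* The LRA is exact only in the linear-response regime; real proteins can
  violate the equal-variance assumption near charged sites.
* One-sided FEP is biased when adjacent ensembles overlap poorly; the
  package reports block-averaged errors but offers no overlap diagnostics.
* The climbing image refines one saddle — paths with multiple competing
  saddles report the highest one found by the band, as the tests on the
  Müller–Brown surface (which has two saddles en route) demonstrate.
* Problem sizes in the tests (grids ≤ 81³, ensembles ≤ 10⁵, 2000² oracle
  grids) were chosen as the package's own desk-scale conditions.
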