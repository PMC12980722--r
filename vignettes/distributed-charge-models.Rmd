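---
title: "Distributed-charge electrostatics and induction models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed-charge electrostatics and induction models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elecff)
```

## The modelling problem

Point partial charges are the workhorse of biomolecular force fields, but a
point is a poor stand-in for an electron cloud: at van der Waals contact the
true electrostatic interaction is screened by charge overlap, and anions in
particular are badly described. `elecff` implements the family of
*intermediate-complexity* electrostatics models that address this without
resorting to multipoles: atomic cores represented by point (or Gaussian, or
Slater) charges, optionally combined with co-located *distributed* charge
carriers — static virtual sites or mobile Drude-like shells — whose Gaussian
or Slater densities provide short-range screening and, for shells,
polarization.

The package covers the whole workflow around such models:

1. **Coulomb kernels** for every pair of carrier types (point, Gaussian,
   1S Slater, 2S Slater), in closed form, with an independent numerical
   oracle.
2. **Split-charge equilibration (SQE)** to generate conformation-independent
   atomic charges from electronegativity/hardness parameters.
3. **ESP machinery**: radial and scaled-vdW-surface grids, constrained linear
   charge fitting, and nonlinear analytic models for single ions.
4. **Dimer energetics**: intermolecular electrostatics, shell relaxation
   (induction), and an attractive Born–Mayer induction-correction term.
5. A **hybrid GA/MC trainer** that fits force-field parameters directly to
   dimer electrostatic and induction energy components.
6. A **synthetic reference generator** that emulates the structure of a
   quantum-chemistry dimer database (distance scans, randomly oriented
   contact dimers, per-frame energy components, selection filters) from a
   known ground-truth model, so the full pipeline is testable offline.

## Units and conventions

Lengths are in Å, charges in e and energies in kJ/mol throughout. The
Coulomb constant is fixed at `KE_COULOMB` = 1389.35458 kJ mol⁻¹ Å e⁻², which
makes all reference values bit-stable; electronegativities (V) and
hardnesses (V/e) convert via 1 eV = 96.4853 kJ/mol, and the hartree-based
exchange filter threshold uses 1 hartree = 2625.4996 kJ/mol.

Density conventions (these differ between codes, so they are spelled out):

* Gaussian: $\rho(r) = q\,\zeta^3 \pi^{-3/2} e^{-\zeta^2 r^2}$, giving the
  point–Gaussian kernel $\mathrm{erf}(\zeta r)/r$.
* 1S Slater: $\rho(r) = q\,\zeta^3/\pi\, e^{-2\zeta r}$, the squared 1S
  Slater wave function; the point–1S kernel is
  $[1 - (1+\zeta r)e^{-2\zeta r}]/r$.
* 2S Slater: $\rho(r) = q\,\zeta^5/(3\pi)\, r^2 e^{-2\zeta r}$.

A minimal-basis-Stockholder valence width $\sigma$ (density
$\propto e^{-r/\sigma}$) maps to these conventions as $\zeta = 1/(2\sigma)$
(`mbis_sigma_to_zeta()`).

## Closed-form kernels and their numerical treatment

All ten pair combinations are supported by `pair_energy()`. The
Gaussian–Gaussian pair collapses to a single kernel with
$\zeta_{\mathrm{eff}} = \zeta_a \zeta_b / \sqrt{\zeta_a^2 + \zeta_b^2}$. The
Slater–Slater closed forms (equal and unequal exponents, including the 2S
combinations) were derived symbolically from the defining double integral
and are validated in the test suite against `quadrature_energy()`, a
fully numerical oracle that rebuilds each density's potential by radial
integration and integrates the pair energy on a 2-D Gauss–Legendre grid with
node-doubling convergence checks. The oracle shares no code with the closed
forms.

Numerical choices worth knowing about:

* **Short range.** The brackets $1 - e^{-2t}P(t)$ of the Slater kernels are
  evaluated as $-\mathrm{expm1}(\log P(t) - 2t)$, which preserves full
  relative precision down to arbitrarily small separations; only $r = 0$ is
  special-cased with the exact overlap limits ($2\zeta/\sqrt{\pi}$ for
  point–Gaussian, $\zeta$ for point–1S, $5\zeta/8$ for 1S–1S, $7\zeta/16$
  for 1S–2S, $93\zeta/256$ for 2S–2S).
* **Nearly equal Slater exponents.** The general unequal-exponent forms
  divide by $(\zeta_a^2-\zeta_b^2)^{3,5,7}$ and lose precision as the
  exponents approach each other. Inside a relative gap of $10^{-3}$ (1S–1S),
  $2\times10^{-2}$ (1S–2S) or $8\times10^{-2}$ (2S–2S) the kernel is instead
  computed by an adaptive semi-analytic radial integral (density of one
  carrier against the exact shell-averaged potential antiderivative of the
  other), accurate to ~1e-9. The same route serves the Gaussian–Slater cross
  pairs, for which no convenient closed form is used.
* **Unequal-exponent short range.** Below $r\,\zeta_{\max} = 10^{-4}$ the
  unequal forms switch to their exact second-order overlap series; the jump
  at the switch is below $10^{-10}$ on the kernel shape (per unit charge
  product).
* **Long range.** Every kernel reverts to $k_e q_a q_b / r$. The Gaussian
  and 1S tails are below $10^{-8}$ relative once $\zeta r \gtrsim 12$; the
  2S–2S tail ($e^{-2t} t^7/1260$) genuinely persists until
  $\zeta r \approx 17$ — a physical property of the fatter 2S density, not a
  numerical artifact.

## Split-charge equilibration

`sqe_assemble()`/`solve_charges()` minimise
$E(p) = \sum_i \chi_i q_i + \tfrac12 \eta_i q_i^2 + \sum_b \Delta\chi_b p_b
+ \tfrac12 \Delta\eta_b p_b^2$ over bond split charges $p$, with
$q = q_{\mathrm{ref}} + T p$. Positive $\eta$ and $\Delta\eta$ make the
bond-space quadratic form positive definite, so the solution is unique and
total charge is conserved *exactly* (charge only flows along bonds). The
reference charges distribute the formal charge uniformly over atoms — a
symmetric, testable choice. Charges depend only on topology and parameters
(no geometric coupling), i.e. they are conformation independent; this is the
plain quadratic SQE and is stated as this package's definition. Bond
directions are canonicalised lexicographically by atom type with the
antisymmetric $\Delta\chi$ sign convention, making the solution invariant to
bond-list order and stored direction.

## ESP grids and fitting

`radial_grid()` reproduces the standard single-ion layout (0 to 4.5 Å in
0.1 Å steps, 46 points); `vdw_layer_grid()` builds the four classic fitting
layers at 1.4–2.0 × the Bondi vdW radius using deterministic
Fibonacci-sphere layouts with interior-point culling (default 5 points/Å²,
configurable). `fit_charges_to_esp()` performs plain (unrestrained) linear
least squares with the total charge enforced exactly by coordinate
elimination and charges tied across topological equivalence classes (colour
refinement); restrained (RESP-style) fitting is intentionally out of scope.

`fit_ion_model()` fits the analytic single-ion models P, P+G, P+G+G, P+1S
and P+1S+2S by constrained nonlinear least squares (Levenberg–Marquardt,
eight deterministic multistarts over exponent/charge magnitudes, ties broken
by the smallest leading exponent). Because every model contains a point
core, grid points at exactly $r = 0$ are excluded from the residual.

## Dimer energies, shells and the induction correction

`electrostatic_energy()` sums kernels over all *intermolecular* site pairs;
intramolecular electrostatics is excluded entirely, because the models are
evaluated against intermolecular reference components only. For 4P water the
oxygen's charge carriers sit on the H–O–H bisector at $r_{OM}$ from the
oxygen on the hydrogen side (TIP4P convention; both the point core and the
distributed carrier are relocated).

`relax_shells()` minimises the intermolecular electrostatic energy plus
harmonic spring terms over the shell displacements of both monomers (mutual
polarization; a single-sided diagnostic mode exists). The spring constant
follows the Drude identity $k = k_e q_V^2/\alpha$. The optimizer is L-BFGS-B
with analytic gradients, followed by a spring-preconditioned fixed-point
polish that drives the maximum gradient component below
$10^{-6}$ kJ mol⁻¹ Å⁻¹ — quasi-Newton alone stalls at the double-precision
resolution of the energy. Displacements beyond 1 Å abort with a
polarization-catastrophe error rather than returning an unphysical energy.
The induction energy is $E(\text{relaxed}) - E(\text{rest}) \le 0$, plus the
attractive Born–Mayer induction-correction term
$V_{ic}(r) = -A_{ic} e^{-b_{ic} r}$ (summed over intermolecular *atom*
pairs, not carrier sites) when the model enables it. The correction is an
acknowledged error sink for higher-order induction, with limited physical
interpretability.

`evaluate_ff()` reports RMSD and mean signed error (model − reference) per
dimer pair and overall, separately for train/test splits, for the
components `Elec`, `Induc` and their sum.

## The GA/MC trainer

`train_ff()` optimises selected force-field parameters against reference
components with a hybrid genetic/Monte-Carlo scheme: tournament selection of
size 2, uniform crossover (probability 0.9), per-gene Gaussian mutation
(s.d. 10% of the bound width, probability 0.15), elitism, and — after each
generation — a Metropolis refinement of every individual (by default 40
steps at a fitness "temperature" of 0.01, proposals with s.d. 1% of the
bound width). The GA operator details are this package's choices, exposed in
`ga_mc_config()`; the standard budget is 20 generations with population 256
(nonpolarizable) or 512 (polarizable). Identical seeds give bit-identical
histories, and the caller's RNG state is restored afterwards.

The fitness is the mean squared deviation of the requested component(s)
plus a chemical-sanity penalty, $k_{pen}\sum q_H^2$ over hydrogens with
negative SQE charges ($k_{pen} = 20000$ per e²). Four targets are supported:
`ESP` (the core charges are refit to the grid inside every evaluation and
the grid residual is scored), `Elec`, `Elec+Induc` (residual of the summed
components) and the simultaneous `Elec,Induc` (both residuals scored without
summing, which buys a balanced model at some cost in the electrostatics
alone). Parameter bounds default to wide chemistry-plausible ranges
(χ ∈ [0,20] V, η ∈ [1,50] V/e, Δχ ∈ [−10,10] V, Δη ∈ [0.1,50] V/e,
ζ ∈ [0.3,10] Å⁻¹, q_V ∈ [−4,0] e, α ∈ [0,5] Å³, A_ic ∈ [0,500] kJ/mol,
b_ic ∈ [0.5,6] Å⁻¹, r_OM ∈ [0,0.3] Å). For polarizable trainings a tighter
α upper bound is advisable: the Drude spring $k_e q_V^2/\alpha$ must exceed
the field gradients at van der Waals contact, and with carrier charges
around −1.5 e that stability threshold sits near α ≈ 2–3 Å³.

The trainer compiles the dataset once (pair distances, site templates,
per-molecule SQE structure) so that a fitness evaluation is a handful of
vectorised kernel calls; geometry-affecting parameters ($r_{OM}$ with 4P
water present) are rejected for this compiled path.

## The synthetic reference generator

`make_ground_truth()` builds an idealised molecule library — water
(0.9572 Å/104.52°), a sodium-like cation, a chloride-like anion, formate and
ammonium — plus a fully specified PC+GV4-style (or, with
`polarizable = TRUE`, PC+GS4-style) force field whose parameters are drawn
deterministically per seed within ±8% of chemistry-typical base values.
Electronegativities are ordered H < C < N < O < Cl so every hydrogen charge
is positive (the ground truth itself is penalty-free), carrier charges are
negative, and the polarizabilities are effective condensed-phase-style
values small enough that the Drude springs resist the fields at van der
Waals contact.

`dimer_scan()` translates the second monomer along the closest-atom vector
of a fixed side-by-side reference pose so the closest-pair separation equals
each requested distance; `random_orientations()` applies uniform quaternion
rotations and slides the monomer along a random approach direction until
the first atom pair touches $u\,(R_i + R_j)$ with $u \sim U[0.9, 1.2]$.
`reference_components()` evaluates the ground truth on every frame: exact
electrostatics; induction by shell relaxation when the ground truth is
polarizable, otherwise a proxy $-0.15\,|E_{el}|\,e^{-0.6 r_{\min}}$ that is
labelled as such in the metadata and never treated as physical; and an
exchange proxy $2.4\times10^5 e^{-3 r_{\min}}$ kJ/mol, calibrated so
repulsion at typical vdW contact is a few tens of kJ/mol and the 0.04
hartree filter bites near 2.6 Å. The proxy exists only to exercise the
selection plumbing — it contains none of exchange's physics. Train/test
splitting is 2:1 by a stable string hash of the frame id, so the split
survives regeneration. `apply_filters()` applies the strict
$r_{\min} < 6$ Å and exchange $< 0.04$ hartree (105.0 kJ/mol) rules;
`synthetic_dataset()` additionally pre-drops frames that these r-min-based
rules would discard *before* computing reference components, since deep
sub-contact frames can polarization-catastrophe a Drude ground truth and
would never survive filtering anyway.

What the generator does **not** emulate: real SAPT components (no exchange
or dispersion physics, no charge transfer), conformational flexibility
(monomers are rigid and idealised), basis-set or method error, and the
chemical breadth of a real training database. Passing the recovery tests
therefore demonstrates that the machinery — kernels, charge generation,
relaxation, training — is correct and self-consistent, not that any
particular parameterisation is accurate for real molecules.

## Problem sizes used in the shipped experiments

The packaged experiments are sized for interactive use: the kernel–oracle
comparison uses 50 random cases; SQE properties are checked over 1000
random tree molecules; the trainer-recovery experiment uses 4 dimer pairs
(~36 frames after filtering) with population 32, 10 generations and 20 MC
steps; the training-target comparison uses 3 polarizable ion/water pairs
(~24 frames) with population 12, 5 generations and 8 MC steps. These
reduced budgets recover the generating energies to well below 0.5 kJ/mol
test RMSD, and the target-semantics ordering (Elec-only ≤ simultaneous on
the Elec component; sum-trained best on the summed component) reproduces at
full strength.

In the trainer-recovery experiment the trainable set deliberately mixes SQE
parameters (χ_H, Δη of the water bond) with carrier parameters (q_V, ζ_V of
the anion): co-located Gaussian carriers with typical widths are
erfc-screened to numerical irrelevance at the sampled distances, so an
experiment that trained only ion carrier parameters would succeed
vacuously. Recovered *parameters* are generally not unique (χ/Δη trade
off; carrier width and charge compensate) — the recovery criterion is the
energy surface, not the parameter vector.

## Known limitations

* No exchange, dispersion or total-interaction-energy model: the package
  covers electrostatics and induction only.
* No Ewald/periodic electrostatics and no forces beyond the shell-relaxation
  gradient.
* The SQE form is the plain quadratic bond-space model; distance-dependent
  couplings are not implemented (a hook exists but is off by default).
* Shell relaxation assumes the harmonic-spring Drude picture; anisotropic or
  field-dependent polarizabilities are out of scope.
* The 4P relocation applies to molecules recognised as water (O + 2 H);
  general off-atom virtual-site geometries (lone pairs, sigma holes) are not
  implemented.
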