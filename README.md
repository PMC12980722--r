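# elecff

Distributed-charge electrostatics and induction models for molecular force
fields, in R.

Point partial charges reproduce molecular electrostatics poorly at short
range — at van der Waals contact the interaction of real electron clouds is
screened by charge overlap, and point-charge models of anions are
qualitatively wrong. `elecff` implements the family of
intermediate-complexity models that fix this without multipoles: atomic
cores (point, Gaussian or Slater charges) optionally combined with
co-located **distributed charge carriers** — static virtual sites or mobile
polarizable Drude-like shells carrying Gaussian or 1S/2S Slater densities —
plus the machinery to parameterise such models **directly against dimer
interaction-energy components** instead of monomer properties.

The package is aimed at force-field developers and method researchers who
want to experiment with charge models, charge-generation schemes and
component-based training loops in a self-contained, fully testable setting.

## What it provides

* **Coulomb kernels** (`pair_energy`, `esp_value`): closed forms for every
  pairing of point, Gaussian, 1S and 2S Slater densities — e.g.
  point–Gaussian `erf(ζr)/r`, point–1S `[1−(1+ζr)e^(−2ζr)]/r`, and the full
  unequal-exponent Slater–Slater family — with finite overlap limits at
  r = 0 and an independent numerical quadrature oracle
  (`quadrature_energy`) used throughout the tests.
* **Split-charge equilibration** (`sqe_charges`): atomic charges from
  electronegativity χ, hardness η and their bond analogues Δχ, Δη by exact
  minimisation of the quadratic SQE energy in bond space; total charge is
  conserved exactly and equivalent atoms get equal charges.
* **ESP tooling**: radial grids, four-layer scaled-vdW-surface grids,
  constrained point/core charge fitting with equivalence classes
  (`fit_charges_to_esp`), and analytic single-ion models P, P+G, P+G+G,
  P+1S, P+1S+2S (`fit_ion_model`).
* **Dimer energetics**: intermolecular electrostatics, mutual Drude-shell
  relaxation with the spring identity k = k_e q_V²/α (`relax_shells`), the
  attractive Born–Mayer induction correction −A_ic e^(−b_ic r), TIP4P-style
  bisector sites for 4P water, and RMSD/MSE evaluation reports
  (`evaluate_ff`).
* **A hybrid GA/MC trainer** (`train_ff`): tournament selection, uniform
  crossover, Gaussian mutation, elitism and per-generation Metropolis
  refinement, with training targets `ESP`, `Elec`, `Elec+Induc` and the
  simultaneous `Elec,Induc`, and a 20000/e² penalty against negative
  hydrogen charges.
* **A synthetic reference generator** (`make_ground_truth`,
  `synthetic_dataset`): dimer distance scans, randomly oriented
  vdW-contact dimers, per-frame Elec/Induc components from a known model,
  an exchange proxy, the strict r_min < 6 Å / exchange < 0.04 hartree
  selection filters and a hash-stable 2:1 train/test split — so the whole
  training pipeline runs and is validated without any quantum-chemistry
  input.

## Worked example

Generate a known ground truth, build its reference dimer dataset, and train
selected parameters back from scratch against the electrostatic component:

```r
library(elecff)

gt <- make_ground_truth(seed = 1)          # PC+GV4-style model + molecules
sqe_charges(gt$molecules$water, gt$ff)
#> [1] -0.2559  0.1279  0.1279

build_site_system(gt$molecules$water, gt$model, gt$ff,
                  sqe_charges(gt$molecules$water, gt$ff))
#> <site_system> water/PC+GV4: 6 sites (3 core, 3 vsite, 0 shell), total q = +0.000000 e

data <- synthetic_dataset(gt, n_scan = 7, n_random = 3, seed = 1,
  pairs = list(c("water", "cation"), c("water", "anion"),
               c("cation", "anion"), c("water", "water")))
data
#> <ref_dataset> 35 frames (23 train / 12 test), 5 molecules; induction is a proxy

spec <- trainable_spec(c("atom.HW.chi", "bond.HW-OW.delta_eta",
                         "atom.Cl.q_V", "atom.Cl.zeta_V"), target = "Elec")
cfg <- ga_mc_config(pop_size = 32, generations = 10, mc_iterations = 20,
                    seed = 1)
fit <- train_ff(gt$ff, gt$model, data, spec, cfg)
fit$report[fit$report$dimer_id == "all", ]
#>  dimer_id split component  n        rmsd          mse
#>       all  test      Elec 12 0.001933618 0.0001262199
#>       all train      Elec 23 0.004706153 0.0009567662
```

The trained model reproduces the held-out electrostatic energies to
~0.002 kJ/mol RMSD: the optimizer has recovered the generating energy
surface (the parameters themselves are not unique — carrier width and
charge compensate).

Kernels are plain functions; the screened point–Gaussian interaction stays
finite at contact and reverts to Coulomb at range:

```r
p <- charge_distribution("point", 1)
g <- charge_distribution("gaussian", -1, zeta = 2)
pair_energy(p, g, c(0, 1, 3))
#> [1] -3135.4375 -1382.8555  -463.1182   # kJ/mol; -k_e/3 at 3 A
```

A thin command-line wrapper (`inst/cli/elecff`) exposes `gen-synthetic`,
`fit-esp`, `fit-ion`, `train`, `eval` and `relax` subcommands over the same
functions.

## Documentation

The methods vignette (`vignettes/distributed-charge-models.Rmd`) describes
the models and their assumptions, the numerical treatment of the kernels,
the trainer design, what the synthetic generator does and does not emulate,
and known limitations.
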