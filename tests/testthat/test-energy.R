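# two bare ions under a point-charge model
ion_pair_frame <- function(d, qa = 1L, qb = -1L) {
  ffa <- force_field(data.frame(type = "A", chi = 5, eta = 10))
  ffb <- force_field(data.frame(type = "B", chi = 5, eta = 10))
  ma <- molecule("a", data.frame(element = "Na", atom_type = "A",
                                 x = 0, y = 0, z = 0), formal_charge = qa)
  mb <- molecule("b", data.frame(element = "Cl", atom_type = "B",
                                 x = d, y = 0, z = 0), formal_charge = qb)
  pc <- model_definition("PC")
  dimer_frame(build_site_system(ma, pc, ffa, qa),
              build_site_system(mb, pc, ffb, qb))
}

test_that("point-ion pairs give the bare Coulomb energy", {
  expect_equal(electrostatic_energy(ion_pair_frame(3)), -KE_COULOMB / 3,
               tolerance = 1e-12)
  # neutral molecules at long range decay to (nearly) nothing
  w <- water_molecule(); ff <- water_ff()
  q <- sqe_charges(w, ff)
  sa <- build_site_system(w, model_definition("PC"), ff, q)
  w2 <- set_coords(w, sweep(coords(w), 2, c(100, 0, 0), `+`))
  sb <- build_site_system(w2, model_definition("PC"), ff, q)
  expect_lt(abs(electrostatic_energy(dimer_frame(sa, sb))), 0.5)
})

test_that("the vectorised dimer energy equals the explicit pair-sum oracle", {
  w <- water_molecule(); ff <- water_ff()
  q <- sqe_charges(w, ff)
  model <- model_definition("PC+GV4")
  sa <- build_site_system(w, model, ff, q)
  w2 <- set_coords(w, rigid_motion(coords(w), seed = 4) / 3 + 3)
  sb <- build_site_system(w2, model, ff, q)
  fr <- dimer_frame(sa, sb)
  # brute force over the 6 x 6 site pair table with scalar pair_energy calls
  brute <- 0
  for (i in seq_len(nrow(sa$sites))) for (j in seq_len(nrow(sb$sites))) {
    si <- sa$sites[i, ]; sj <- sb$sites[j, ]
    di <- sqrt((si$x - sj$x)^2 + (si$y - sj$y)^2 + (si$z - sj$z)^2)
    a <- charge_distribution(si$kind, si$q,
                             zeta = if (si$kind == "point") NULL else si$zeta)
    b <- charge_distribution(sj$kind, sj$q,
                             zeta = if (sj$kind == "point") NULL else sj$zeta)
    brute <- brute + pair_energy(a, b, di)
  }
  expect_equal(electrostatic_energy(fr), brute, tolerance = 1e-9)
})

test_that("coincident intermolecular point pairs are reported by name", {
  expect_error(electrostatic_energy(ion_pair_frame(1e-14)), "degenerate|coincident")
})

test_that("the induction correction is attractive and monotone", {
  fr <- ion_pair_frame(1)
  expect_identical(induction_correction(fr, 0, 2), 0)
  expect_equal(induction_correction(fr, 100, 2), -100 * exp(-2),
               tolerance = 1e-12)
  rs <- c(1, 1.5, 2.5, 4, 6)
  v <- sapply(rs, function(d) induction_correction(ion_pair_frame(d), 80, 1.7))
  expect_true(all(v <= 0))
  expect_true(all(diff(v) > 0))   # increasing towards zero
  expect_error(induction_correction(fr, -1, 2), "A_ic")
})

# shell on a neutral atom next to a bare point charge
shell_probe <- function(d, alpha = 1, q_shell = -1, Q = 1) {
  ff <- force_field(data.frame(type = "S", chi = 5, eta = 10, q_V = q_shell,
                               zeta_V = 2, zeta = 2, alpha = alpha))
  msh <- molecule("sh", data.frame(element = "Ar", atom_type = "S",
                                   x = 0, y = 0, z = 0))
  mq <- molecule("pq", data.frame(element = "Na", atom_type = "P",
                                  x = d, y = 0, z = 0),
                 formal_charge = as.integer(Q))
  shell_model <- model_definition("shell-probe", core_kind = "point",
                                  shell = TRUE, water_sites = "3P")
  ffp <- force_field(data.frame(type = "P", chi = 5, eta = 10))
  dimer_frame(build_site_system(msh, shell_model, ff, 0),
              build_site_system(mq, model_definition("PC"), ffp, Q))
}

test_that("an isolated shell stays at rest with zero induction energy", {
  # neutral, zero-charge partner: no field, no displacement
  fr <- shell_probe(5, Q = 0)
  rel <- relax_shells(fr)
  expect_equal(rel$e_induction, 0, tolerance = 1e-10)
  expect_equal(max(rel$displacements), 0, tolerance = 1e-8)
})

test_that("weak-field shell relaxation reproduces the Drude closed form", {
  errs <- sapply(c(8, 10, 12), function(d) {
    rel <- relax_shells(shell_probe(d))
    drude <- -KE_COULOMB / (2 * d^4)   # -k_e Q^2 alpha / (2 d^4)
    abs(rel$e_induction - drude) / abs(drude)
  })
  expect_true(all(errs < 0.01))
  expect_true(all(diff(errs) < 0))   # error shrinks with distance
  # halving alpha (doubling the spring) halves the weak-field response
  e1 <- relax_shells(shell_probe(10, alpha = 1))$e_induction
  e2 <- relax_shells(shell_probe(10, alpha = 0.5))$e_induction
  expect_equal(e1 / e2, 2, tolerance = 5e-3)
})

test_that("relaxation lowers the energy and is order-symmetric", {
  gt <- make_ground_truth(5, polarizable = TRUE)
  w <- gt$molecules$water; an <- gt$molecules$anion
  qw <- sqe_charges(w, gt$ff)
  an2 <- an; an2$atoms$x <- 3.2
  sa <- build_site_system(w, gt$model, gt$ff, qw)
  sb <- build_site_system(an2, gt$model, gt$ff, -1)
  f1 <- dimer_frame(sa, sb)
  f2 <- dimer_frame(sb, sa)
  r1 <- relax_shells(f1); r2 <- relax_shells(f2)
  expect_lte(r1$e_induction, 0)
  expect_equal(r1$e_induction, r2$e_induction, tolerance = 1e-10)
  expect_equal(r1$e_elec_rest, r2$e_elec_rest, tolerance = 1e-10)
  # single-sided relaxation responds less than mutual relaxation
  r_one <- relax_shells(f1, mutual = FALSE)
  expect_gte(r_one$e_induction, r1$e_induction - 1e-12)
})

test_that("evaluation reports detect bias and respect RMSD >= |MSE|", {
  gt <- make_ground_truth(3)
  data <- synthetic_dataset(gt, n_scan = 4, n_random = 2, seed = 3)
  # self-evaluation of the generator is exact
  rep0 <- evaluate_ff(gt$ff, gt$model, data, components = "Elec")
  expect_lt(max(rep0$rmsd), 1e-9)
  expect_lt(max(abs(rep0$mse)), 1e-9)
  # a constant +c offset appears as MSE = c, RMSD = c
  data2 <- data
  data2$components$E_elec_kJmol <- data2$components$E_elec_kJmol - 2.5
  rep2 <- evaluate_ff(gt$ff, gt$model, data2, components = "Elec")
  expect_equal(unique(round(rep2$mse, 9)), 2.5)
  expect_equal(unique(round(rep2$rmsd, 9)), 2.5)
  # Jensen: RMSD >= |MSE| for arbitrary perturbed references
  rng <- elecff:::.local_rng(31)
  for (i in 1:200) {
    n <- 3 + floor(rng(1) * 40)
    e <- 10 * (rng(n) - 0.5)
    expect_gte(sqrt(mean(e^2)), abs(mean(e)))
  }
  rep3 <- evaluate_ff(gt$ff, gt$model, data2, components = "Elec")
  expect_true(all(rep3$rmsd >= abs(rep3$mse) - 1e-12))
})
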