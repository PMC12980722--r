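test_that("radial grids enumerate the documented point layouts", {
  expect_equal(nrow(radial_grid(4.5, 0.1)$points), 46L)
  expect_equal(radial_grid(1.0, 0.5)$points[, "x"], c(0, 0.5, 1.0))
  expect_equal(unname(radial_grid(0.4, 0.5)$points[, "x"]), 0)  # dr > r_max
  expect_error(radial_grid(-1, 0.1))
})

test_that("vdW-layer grids respect radii, layers and culling", {
  ion <- molecule("ion", data.frame(element = "X", atom_type = "X",
                                    x = 0, y = 0, z = 0, vdw_radius = 1.5))
  g <- vdw_layer_grid(ion, factors = c(1.4, 2.0), density = 3)
  r <- sqrt(rowSums(g$points^2))
  expect_true(all(abs(r - 2.1) < 1e-9 | abs(r - 3.0) < 1e-9))
  expect_setequal(round(unique(round(r, 6)), 6), c(2.1, 3.0))

  # two overlapping atoms: no kept point strictly inside either scaled sphere
  dia <- molecule("d2", data.frame(element = c("C", "C"),
                                   atom_type = c("C", "C"),
                                   x = c(0, 1.4), y = 0, z = 0),
                  bonds = matrix(c(1L, 2L), ncol = 2))
  g2 <- vdw_layer_grid(dia, factors = c(1.4), density = 4)
  d1 <- sqrt(rowSums(g2$points^2))
  d2 <- sqrt(rowSums(sweep(g2$points, 2, c(1.4, 0, 0))^2))
  expect_true(all(pmax(d1, d2) >= 1.4 * 1.7 * (1 - 1e-9)))

  # four default layers for water
  g3 <- vdw_layer_grid(water_molecule(), density = 2)
  dmin <- apply(g3$points, 1, function(p)
    min(sqrt(colSums((t(coords(water_molecule())) - p)^2)) /
          water_molecule()$atoms$vdw_radius))
  expect_equal(sort(unique(round(dmin, 6))), c(1.4, 1.6, 1.8, 2.0),
               tolerance = 1e-5)
  expect_error(vdw_layer_grid(water_molecule(), factors = c(2, 1.4)),
               "ascending")
})

test_that("ESP point-charge fitting recovers a generating water model", {
  w <- water_molecule()
  ff <- water_ff()
  model <- model_definition("PC")
  q_true <- c(-0.834, 0.417, 0.417)
  sys <- build_site_system(w, model, ff, q_true)
  grid <- vdw_layer_grid(w, density = 5)
  grid$values <- model_esp(sys, grid)
  fit <- fit_charges_to_esp(w, model, ff, grid, Q_total = 0)
  expect_equal(fit$charges, q_true, tolerance = 1e-6)
  expect_lt(fit$rmsd, 1e-8)
  # hydrogens share one equivalence class
  expect_equal(atom_equivalence_classes(w), c(1L, 2L, 2L))
})

test_that("the total-charge constraint is exact and the null fit is null", {
  w <- water_molecule()
  ff <- water_ff()
  model <- model_definition("PC")
  grid <- vdw_layer_grid(w, density = 4)
  grid$values <- rep(0, nrow(grid$points))
  fit <- fit_charges_to_esp(w, model, ff, grid, Q_total = 0)
  expect_equal(fit$charges, c(0, 0, 0), tolerance = 1e-10)
  grid$values <- stats::qnorm(elecff:::.local_rng(5)(nrow(grid$points)))
  fit2 <- fit_charges_to_esp(w, model, ff, grid, Q_total = -1)
  expect_equal(sum(fit2$charges), -1, tolerance = 1e-12)
})

test_that("fit residuals are invariant under rigid motion", {
  w <- water_molecule()
  ff <- water_ff()
  model <- model_definition("PC")
  sys <- build_site_system(w, model, ff, c(-0.8, 0.4, 0.4))
  grid <- vdw_layer_grid(w, density = 4)
  grid$values <- model_esp(sys, grid) +
    0.5 * sin(seq_len(nrow(grid$points)))  # imperfect reference
  fit <- fit_charges_to_esp(w, model, ff, grid, Q_total = 0)

  both <- rigid_motion(rbind(coords(w), grid$points), seed = 3)
  w2 <- set_coords(w, both[1:3, ])
  grid2 <- grid
  grid2$points <- both[-(1:3), ]
  fit2 <- fit_charges_to_esp(w2, model, ff, grid2, Q_total = 0)
  expect_equal(fit$rmsd, fit2$rmsd, tolerance = 1e-10)
  expect_equal(fit$charges, fit2$charges, tolerance = 1e-8)
})

test_that("analytic ion-model fits recover in-family parameters", {
  # reference generated by a P+1S model
  q_core <- 8; q_s <- -9; zeta <- 2.2
  r <- radial_grid(4.5, 0.1)$points[, "x"]
  core <- charge_distribution("point", q_core)
  val <- charge_distribution("slater1s", q_s, zeta = zeta)
  phi <- ifelse(r > 0, KE_COULOMB * q_core / r, NA) + esp_value(val, r)
  ref <- data.frame(r = r, phi = phi)[r > 0, ]
  fit <- fit_ion_model(ref, "P+1S", Q = -1, range = c(0, 4.5))
  expect_equal(unname(fit$charges["core"]), q_core, tolerance = 1e-4)
  expect_equal(unname(fit$charges[2]), q_s, tolerance = 1e-4)
  expect_equal(fit$zetas, zeta, tolerance = 1e-4)
  expect_lt(fit$rmsd, 1e-6)
})

test_that("a bare point charge cannot fit a distributed reference", {
  r <- seq(0.5, 4.5, by = 0.1)
  g <- charge_distribution("gaussian", -2, zeta = 1.2)
  p <- charge_distribution("point", 1)
  ref <- data.frame(r = r, phi = esp_value(p, r) + esp_value(g, r))
  fit <- fit_ion_model(ref, "P", Q = -1, range = c(0.5, 4.5))
  expect_gt(fit$rmsd, 1)
})

test_that("nested ion models have monotone fit residuals", {
  # halide-like synthetic reference: core + two distributed shells
  r <- seq(0.2, 4.5, by = 0.05)
  phi <- esp_value(charge_distribution("point", 9), r) +
    esp_value(charge_distribution("slater1s", -7, zeta = 2.6), r) +
    esp_value(charge_distribution("slater2s", -3, zeta = 1.1), r)
  ref <- data.frame(r = r, phi = phi)
  rms <- sapply(c("P", "P+G", "P+G+G", "P+1S", "P+1S+2S"), function(k)
    fit_ion_model(ref, k, Q = -1, range = c(0.2, 4.5))$rmsd)
  expect_lte(rms[["P+G"]], rms[["P"]] * (1 + 1e-9))
  expect_lte(rms[["P+G+G"]], rms[["P+G"]] * (1 + 1e-9))
  expect_lte(rms[["P+1S"]], rms[["P"]] * (1 + 1e-9))
  expect_lte(rms[["P+1S+2S"]], rms[["P+1S"]] * (1 + 1e-9))
  # in-family nested fit is essentially exact
  expect_lt(rms[["P+1S+2S"]], 1e-4)
})

test_that("short-range-trained fits beat full-range fits on their window", {
  # mirror of the inner/outer fitting-window trade-off: a model fitted on
  # [2, 4.5] does at least as well there as the [0, 4.5] fit restricted to it
  r <- seq(0.1, 4.5, by = 0.05)
  phi <- esp_value(charge_distribution("point", 9), r) +
    esp_value(charge_distribution("slater1s", -7, zeta = 2.4), r) +
    esp_value(charge_distribution("slater2s", -3, zeta = 0.9), r)
  ref <- data.frame(r = r, phi = phi)
  fit_vdw <- fit_ion_model(ref, "P+G", Q = -1, range = c(2, 4.5))
  fit_full <- fit_ion_model(ref, "P+G", Q = -1, range = c(0.1, 4.5))
  sel <- ref$r >= 2
  phi_model <- function(fit) {
    qs <- fit$charges[-1]; zs <- fit$zetas
    out <- esp_value(charge_distribution("point", unname(fit$charges["core"])),
                     ref$r[sel])
    for (k in seq_along(zs))
      out <- out + esp_value(charge_distribution("gaussian", unname(qs[k]),
                                                 zeta = zs[k]), ref$r[sel])
    out
  }
  rms_w <- sqrt(mean((phi_model(fit_vdw) - ref$phi[sel])^2))
  rms_f <- sqrt(mean((phi_model(fit_full) - ref$phi[sel])^2))
  expect_lte(rms_w, rms_f * (1 + 1e-9))
})
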