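test_that("definitional Coulomb values and overlap limits are exact", {
  p <- charge_distribution("point", 1)
  expect_equal(pair_energy(p, p, 1), KE_COULOMB)
  expect_equal(esp_value(p, 2), KE_COULOMB / 2)

  g <- charge_distribution("gaussian", 1, zeta = 1)
  expect_equal(pair_energy(p, g, 0), 2 * KE_COULOMB / sqrt(pi), tolerance = 1e-12)

  s <- charge_distribution("slater1s", -1, zeta = 2)
  expect_equal(pair_energy(p, s, 0), -KE_COULOMB * 2, tolerance = 1e-12)
  expect_equal(esp_value(s, 0), -KE_COULOMB * 2, tolerance = 1e-12)

  s2 <- charge_distribution("slater2s", 1, zeta = 3)
  expect_equal(pair_energy(p, s2, 0), KE_COULOMB * 3 / 2, tolerance = 1e-12)

  # equal-exponent Slater-Slater overlap limits: 5z/8, 7z/16, 93z/256
  s1 <- charge_distribution("slater1s", 1, zeta = 2)
  expect_equal(pair_energy(s1, s1, 0), KE_COULOMB * 5 * 2 / 8, tolerance = 1e-10)
  expect_equal(pair_energy(s1, charge_distribution("slater2s", 1, zeta = 2), 0),
               KE_COULOMB * 7 * 2 / 16, tolerance = 1e-10)
  s22 <- charge_distribution("slater2s", 1, zeta = 2)
  expect_equal(pair_energy(s22, s22, 0), KE_COULOMB * 93 * 2 / 256, tolerance = 1e-10)

  # gaussian-gaussian collapses to a single kernel with zeta_eff = sqrt(2)
  g2 <- charge_distribution("gaussian", 1, zeta = 2)
  erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  expect_equal(pair_energy(g2, g2, 1.3), KE_COULOMB * erf_(sqrt(2) * 1.3) / 1.3,
               tolerance = 1e-12)
})

test_that("point-point singularity and domain errors are raised", {
  p <- charge_distribution("point", 1)
  expect_error(pair_energy(p, p, 0), "singular")
  expect_error(esp_value(p, 0), "singular")
  expect_error(pair_energy(p, p, -1), "finite and >= 0")
  expect_error(charge_distribution("gaussian", 1), "zeta")
  expect_error(charge_distribution("gaussian", 1, zeta = -2), "zeta")
  expect_error(charge_distribution("point", 1, zeta = 2), "no width")
})

test_that("pair energies are symmetric and match the long-range monopole", {
  kinds <- c("gaussian", "slater1s", "slater2s")
  rng <- elecff:::.local_rng(42)
  for (i in 1:20) {
    ka <- kinds[1 + floor(rng(1) * 3)]; kb <- kinds[1 + floor(rng(1) * 3)]
    za <- 0.5 + 5.5 * rng(1); zb <- 0.5 + 5.5 * rng(1)
    a <- charge_distribution(ka, 1.3, zeta = za)
    b <- charge_distribution(kb, -0.7, zeta = zb)
    r <- 0.2 + 7.8 * rng(1)
    expect_identical(pair_energy(a, b, r), pair_energy(b, a, r))
    # monopole limit once zeta_min * r > 12
    rfar <- 15 / min(za, zb)
    expect_equal(pair_energy(a, b, rfar), KE_COULOMB * a$q * b$q / rfar,
                 tolerance = 1e-8)
    expect_equal(esp_value(a, rfar) * rfar, KE_COULOMB * a$q, tolerance = 1e-8)
  }
})

test_that("like-charge distributed kernels are screened below point-point", {
  p <- charge_distribution("point", 1)
  rs <- c(0.3, 0.8, 1.5, 3, 6)
  for (kind in c("gaussian", "slater1s", "slater2s")) {
    for (z in c(0.7, 2, 5)) {
      a <- charge_distribution(kind, 1, zeta = z)
      expect_true(all(pair_energy(a, a, rs) <= pair_energy(p, p, rs)))
      expect_true(all(pair_energy(p, a, rs) <= pair_energy(p, p, rs)))
    }
  }
})

test_that("kernel shapes are continuous across the small-argument switches", {
  # continuity of the shape f = E/(k_e qa qb), per unit charge product
  shape <- function(a, b, r) pair_energy(a, b, r) / KE_COULOMB
  # equal-exponent Slater brackets approach their overlap limit smoothly
  for (kind in c("slater1s", "slater2s")) {
    z <- 2.5
    a <- charge_distribution(kind, 1, zeta = z)
    expect_lt(abs(shape(a, a, 1e-9) - shape(a, a, 0)), 1e-10)
  }
  # unequal-exponent forms switch to the overlap series at r * zmax = 1e-4
  a <- charge_distribution("slater1s", 1, zeta = 1.1)
  b <- charge_distribution("slater1s", 1, zeta = 4.2)
  r0 <- 1e-4 / 4.2
  expect_lt(abs(shape(a, b, r0 * (1 + 1e-9)) - shape(a, b, r0 * (1 - 1e-9))),
            1e-10)
  c2 <- charge_distribution("slater2s", 1, zeta = 3.8)
  r0 <- 1e-4 / 3.8
  expect_lt(abs(shape(a, c2, r0 * (1 + 1e-9)) - shape(a, c2, r0 * (1 - 1e-9))),
            1e-10)
})

test_that("quadrature oracle self-checks and degenerate cases behave", {
  # narrow gaussians reduce to point-point
  g <- charge_distribution("gaussian", 1, zeta = 20)
  expect_equal(quadrature_energy(g, g, 3), KE_COULOMB / 3, tolerance = 1e-8)
  # null charge short-circuits
  z <- charge_distribution("gaussian", 0, zeta = 1)
  expect_identical(quadrature_energy(z, g, 2), 0)
  # oracle vs closed form for a point-Slater pair
  p <- charge_distribution("point", 1)
  s <- charge_distribution("slater1s", 1, zeta = 2)
  expect_equal(quadrature_energy(p, s, 1.2), pair_energy(p, s, 1.2),
               tolerance = 1e-6)
  # a truncation radius that loses charge is reported, not silently accepted
  tight <- quadrature_spec(cutoff_factor = 2)
  s1 <- charge_distribution("slater1s", 1, zeta = 1)
  expect_error(quadrature_energy(s1, s1, 2, tight), "cutoff_factor")
})

test_that("a frozen Slater-Slater value matches the quadrature oracle", {
  # regression value computed once with quadrature_spec(96, 64, 96)
  a <- charge_distribution("slater1s", 1, zeta = 1.5)
  expect_equal(pair_energy(a, a, 2.0), 666.4806, tolerance = 1e-6)
  expect_equal(quadrature_energy(a, a, 2.0), 666.4806, tolerance = 1e-6)
})

test_that("the Gaussian ESP field satisfies the Poisson equation", {
  # 7-point finite-difference Laplacian of Phi reproduces -4 pi k_e rho
  zeta <- 1.6
  a <- charge_distribution("gaussian", -1.2, zeta = zeta)
  r0 <- 1 / zeta
  h <- 1e-3
  phi_at <- function(x, y, z) esp_value(a, sqrt(x^2 + y^2 + z^2))
  lap <- (phi_at(r0 + h, 0, 0) + phi_at(r0 - h, 0, 0) +
          phi_at(r0, h, 0) + phi_at(r0, -h, 0) +
          phi_at(r0, 0, h) + phi_at(r0, 0, -h) - 6 * phi_at(r0, 0, 0)) / h^2
  rho <- a$q * zeta^3 / pi^1.5 * exp(-(zeta * r0)^2)
  expect_equal(lap, -4 * pi * KE_COULOMB * rho, tolerance = 1e-3)
})
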