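#' Quadrature specification for the numerical Coulomb oracle
#'
#' Controls the node counts of [quadrature_energy()]. The oracle never reuses
#' the closed-form kernels: the potential of one distribution is rebuilt from
#' its density by radial integration and the pair energy is then a 2-D
#' (radius x polar angle) Gauss-Legendre integral over the other density.
#'
#' @param n_radial outer radial nodes over the first density
#' @param n_angular polar-angle nodes
#' @param n_inner nodes per radial sub-integral when building the potential
#' @param cutoff_factor densities are truncated where the enclosed charge
#'   reaches at least `1 - 1e-7` of the total; the cutoff is
#'   `cutoff_factor / zeta` for Slater and `cutoff_factor / (2 zeta)` for
#'   Gaussian widths
#' @return a `quadrature_spec` object
#' @export
quadrature_spec <- function(n_radial = 96, n_angular = 64, n_inner = 96,
                            cutoff_factor = 22) {
  stopifnot(n_radial >= 8, n_angular >= 8, n_inner >= 8, cutoff_factor > 0)
  structure(list(n_radial = n_radial, n_angular = n_angular,
                 n_inner = n_inner, cutoff_factor = cutoff_factor,
                 scheme = "gauss-legendre-2d"),
            class = "quadrature_spec")
}

# truncation radius holding >= 1 - 1e-7 of the charge
.density_cutoff <- function(kind, z, factor) {
  switch(kind,
    gaussian = factor / (2 * z),
    slater1s = factor / (2 * z),
    slater2s = factor / (2 * z) * 1.5,
    stop("no density cutoff for kind: ", kind))
}

# numeric potential (per unit charge, without KE_COULOMB) of a distributed
# density at distances s (vector), built purely from the radial density:
# phi(s) = (1/s) int_0^s 4 pi u^2 rho du + int_s^cut 4 pi u rho du
.phi_numeric <- function(kind, z, s, n_inner, cutoff) {
  rho <- .density_radial(kind, z)
  gl <- pracma::gaussLegendre(n_inner, 0, 1)
  x <- gl$x; w <- gl$w
  vapply(s, function(si) {
    inner <- if (si > 0) {
      u <- si * x
      si * sum(w * 4 * pi * u^2 * rho(u)) / si
    } else 0
    outer <- if (si < cutoff) {
      u <- si + (cutoff - si) * x
      (cutoff - si) * sum(w * 4 * pi * u * rho(u))
    } else 0
    if (si > 0) inner + outer else outer
  }, numeric(1))
}

.quadrature_once <- function(a, b, r, spec) {
  # point charges interact through the partner's numeric potential
  if (a$kind == "point" && b$kind == "point")
    return(KE_COULOMB * a$q * b$q / r)
  if (a$kind == "point" || b$kind == "point") {
    if (a$kind == "point") { p <- a; d <- b } else { p <- b; d <- a }
    cut <- .density_cutoff(d$kind, d$zeta, spec$cutoff_factor)
    phi <- .phi_numeric(d$kind, d$zeta, r, spec$n_inner, cut)
    return(KE_COULOMB * p$q * d$q * phi)
  }
  cut_a <- .density_cutoff(a$kind, a$zeta, spec$cutoff_factor)
  cut_b <- .density_cutoff(b$kind, b$zeta, spec$cutoff_factor)
  rho_a <- .density_radial(a$kind, a$zeta)
  glr <- pracma::gaussLegendre(spec$n_radial, 0, cut_a)
  gla <- pracma::gaussLegendre(spec$n_angular, -1, 1)  # cos(theta)
  u <- glr$x; wu <- glr$w
  ct <- gla$x; wt <- gla$w
  # distances from the second centre to every (u, theta) node
  d2 <- outer(u^2, rep(1, length(ct))) + r^2 -
    2 * r * outer(u, ct)
  d2[d2 < 0] <- 0
  dd <- sqrt(d2)
  phi_b <- .phi_numeric(b$kind, b$zeta, as.vector(dd), spec$n_inner, cut_b)
  phi_b <- matrix(phi_b, nrow = length(u))
  val <- sum((wu * 2 * pi * u^2 * rho_a(u)) * (phi_b %*% wt))
  KE_COULOMB * a$q * b$q * val
}

#' Numerical pair energy of two charge distributions (oracle)
#'
#' Brute-force numerical realisation of the Coulomb integral between two
#' spherical charge distributions, reduced to nested 1-D/2-D quadratures via
#' the spherical symmetry of each density. Serves as the independent oracle
#' for validating the closed-form kernels in [pair_energy()]. By default the
#' result is verified by node doubling; disagreement beyond `1e-7` relative
#' raises an accuracy error.
#'
#' @param a,b `charge_distribution` objects
#' @param r separation in Angstrom (scalar)
#' @param spec a [quadrature_spec()]
#' @param check verify convergence by node doubling (default `TRUE`)
#' @return energy in kJ/mol
#' @export
quadrature_energy <- function(a, b, r, spec = quadrature_spec(), check = TRUE) {
  stopifnot(inherits(a, "charge_distribution"), inherits(b, "charge_distribution"),
            inherits(spec, "quadrature_spec"), length(r) == 1L, r >= 0)
  if (a$q == 0 || b$q == 0) return(0)
  if (a$kind == "point" && b$kind == "point" && r == 0)
    stop("point-point interaction is singular at r = 0")
  # verify the truncated densities hold essentially all charge
  for (d in list(a, b)) {
    if (d$kind == "point") next
    cut <- .density_cutoff(d$kind, d$zeta, spec$cutoff_factor)
    rho <- .density_radial(d$kind, d$zeta)
    gl <- pracma::gaussLegendre(4 * spec$n_inner, 0, cut)
    qt <- sum(gl$w * 4 * pi * gl$x^2 * rho(gl$x))
    if (qt < 0.999999)
      stop("truncated density integral ", format(qt), " < 0.999999; increase cutoff_factor")
  }
  v1 <- .quadrature_once(a, b, r, spec)
  if (!check) return(v1)
  # node doubling until two successive levels agree; diffuse densities with
  # large truncation radii may need more than one refinement
  for (level in 1:3) {
    spec2 <- spec
    spec2$n_radial <- 2L^level * spec$n_radial
    spec2$n_angular <- 2L^level * spec$n_angular
    spec2$n_inner <- 2L^level * spec$n_inner
    v2 <- .quadrature_once(a, b, r, spec2)
    if (abs(v1 - v2) / max(abs(v2), 1) <= 1e-7) return(v2)
    v1 <- v2
  }
  stop(sprintf("quadrature not converged under node doubling: %.10g vs %.10g",
               v1, v2))
}
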