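#' Radial ESP grid
#'
#' Collinear evaluation points at distances `0, dr, 2 dr, ..., r_max` from the
#' origin, the layout used for analytic single-ion models. The point at
#' `r = 0` is only usable with distributed charge models (a point charge's
#' potential is singular there).
#'
#' @param r_max outermost distance (Angstrom)
#' @param dr spacing (Angstrom)
#' @return an `esp_grid`: points matrix, optional values, provenance tag
#' @export
#' @examples
#' nrow(radial_grid(4.5, 0.1)$points)  # 46 points
radial_grid <- function(r_max, dr) {
  stopifnot(r_max > 0, dr > 0)
  r <- seq(0, r_max, by = dr)
  pts <- cbind(x = r, y = 0, z = 0)
  structure(list(points = pts, values = NULL, provenance = "radial"),
            class = "esp_grid")
}

#' ESP grid on scaled van der Waals surfaces
#'
#' For each scale factor f, quasi-uniform points on the outer surface of the
#' union of atom spheres of radius `f * R_vdw`: per-atom Fibonacci-sphere
#' layouts with points culled when they fall inside any atom's scaled sphere
#' (up to 1e-9 slack). Deterministic for a given density. The default factors
#' 1.4-2.0 give the four standard fitting layers.
#'
#' @param mol a `molecule`
#' @param factors ascending scale factors, all > 1
#' @param density target point density (points per square Angstrom)
#' @return an `esp_grid` with provenance `"vdw_layers"`
#' @export
vdw_layer_grid <- function(mol, factors = c(1.4, 1.6, 1.8, 2.0), density = 5) {
  stopifnot(inherits(mol, "molecule"))
  if (nrow(mol$atoms) == 0L) stop("empty molecule")
  if (is.unsorted(factors) || any(factors <= 1))
    stop("factors must be ascending and > 1")
  xyz <- coords(mol)
  rv <- mol$atoms$vdw_radius
  keep <- list()
  for (f in factors) {
    for (i in seq_len(nrow(xyz))) {
      R <- f * rv[i]
      n <- max(16L, ceiling(density * 4 * pi * R^2))
      pts <- .fibonacci_sphere(n) * R
      pts <- sweep(pts, 2, xyz[i, ], `+`)
      inside <- rep(FALSE, nrow(pts))
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        dj <- sqrt(colSums((t(pts) - xyz[j, ])^2))
        inside <- inside | dj < f * rv[j] * (1 - 1e-9)
      }
      keep[[length(keep) + 1L]] <- pts[!inside, , drop = FALSE]
    }
  }
  pts <- do.call(rbind, keep)
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, values = NULL, provenance = "vdw_layers"),
            class = "esp_grid")
}

# deterministic quasi-uniform points on the unit sphere
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Model ESP of a site system on grid points
#'
#' @param sys a `site_system`
#' @param points n x 3 matrix or an `esp_grid`
#' @return potential in kJ/(mol e) at each point
#' @export
model_esp <- function(sys, points) {
  if (inherits(points, "esp_grid")) points <- points$points
  stopifnot(inherits(sys, "site_system"), ncol(points) == 3)
  s <- sys$sites
  out <- numeric(nrow(points))
  for (k in seq_len(nrow(s))) {
    d <- sqrt((points[, 1] - s$x[k])^2 + (points[, 2] - s$y[k])^2 +
                (points[, 3] - s$z[k])^2)
    out <- out + KE_COULOMB * s$q[k] *
      .shape_dispatch("point", NA_real_, s$kind[k], s$zeta[k], d)
  }
  out
}

#' Topological equivalence classes of atoms
#'
#' Partition atoms by iterative neighbourhood colour refinement starting from
#' (element, atom_type, degree); chemically identical atoms (e.g. the
#' hydrogens of a methyl group) end up in the same class. Used as the default
#' charge-equivalencing policy in ESP fits.
#'
#' @param mol a `molecule`
#' @return integer vector of class labels (1-based, contiguous)
#' @export
atom_equivalence_classes <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  col <- as.integer(factor(paste(mol$atoms$element, mol$atoms$atom_type,
                                 lengths(adj))))
  repeat {
    sig <- vapply(seq_len(n), function(i)
      paste(col[i], paste(sort(col[adj[[i]]]), collapse = ","), sep = "|"),
      character(1))
    newcol <- as.integer(factor(sig))
    if (identical(newcol, col)) break
    col <- newcol
  }
  as.integer(factor(col, levels = unique(col)))
}

#' Fit charges to a reference ESP under a total-charge constraint
#'
#' Linear least squares for one charge per equivalence class, minimising the
#' squared deviation of the model ESP from the reference over all grid
#' points. The total-charge constraint is exact: the last class's charge is
#' eliminated rather than penalised. Distributed carriers (virtual sites) with
#' fixed charges contribute a constant offset to the design.
#'
#' @param mol a `molecule`
#' @param model a `model_definition` (its cores carry the fitted charges;
#'   any virtual sites keep the `q_V`, `zeta_V` of `ff`)
#' @param ff a `force_field` (widths and `q_V` for distributed carriers)
#' @param grid an `esp_grid` with reference `values`
#' @param Q_total total charge to enforce (e)
#' @param classes optional integer vector of equivalence classes; default
#'   [atom_equivalence_classes()]
#' @return list with `charges` (per atom, e), `class_charges`, `rmsd`
#'   (kJ/(mol e)) and the design condition number
#' @export
fit_charges_to_esp <- function(mol, model, ff, grid, Q_total,
                               classes = NULL) {
  stopifnot(inherits(grid, "esp_grid"), !is.null(grid$values))
  pts <- grid$points
  phi_ref <- grid$values
  stopifnot(length(phi_ref) == nrow(pts), all(is.finite(phi_ref)))
  n <- nrow(mol$atoms)
  if (is.null(classes)) classes <- atom_equivalence_classes(mol)
  stopifnot(length(classes) == n)
  nc <- max(classes)
  if (nrow(pts) < nc) stop("fewer grid points than free parameters")

  # per-atom basis: potential of a unit core charge at each grid point, plus
  # the fixed offset of any q_V carriers (core charge = q_atom - q_V)
  sys0 <- build_site_system(mol, model, ff, .uniform_charges(mol))
  core <- sys0$sites[sys0$sites$role == "core", ]
  basis <- matrix(0, nrow(pts), n)
  offset <- numeric(nrow(pts))
  for (i in seq_len(n)) {
    ci <- core[core$parent == i, ]
    d <- sqrt((pts[, 1] - ci$x)^2 + (pts[, 2] - ci$y)^2 + (pts[, 3] - ci$z)^2)
    basis[, i] <- KE_COULOMB *
      .shape_dispatch("point", NA_real_, ci$kind, ci$zeta, d)
  }
  other <- sys0$sites[sys0$sites$role != "core", ]
  if (nrow(other)) {
    for (k in seq_len(nrow(other))) {
      d <- sqrt((pts[, 1] - other$x[k])^2 + (pts[, 2] - other$y[k])^2 +
                  (pts[, 3] - other$z[k])^2)
      offset <- offset + KE_COULOMB * other$q[k] *
        .shape_dispatch("point", NA_real_, other$kind[k], other$zeta[k], d)
      # the matching core deficit (-q_V) rides on the atomic basis column:
      # core charge is q_atom - q_V, handled via the offset below
    }
    qv <- other$q
    for (k in seq_len(nrow(other))) {
      i <- other$parent[k]
      ci <- core[core$parent == i, ]
      d <- sqrt((pts[, 1] - ci$x)^2 + (pts[, 2] - ci$y)^2 + (pts[, 3] - ci$z)^2)
      offset <- offset - KE_COULOMB * qv[k] *
        .shape_dispatch("point", NA_real_, ci$kind, ci$zeta, d)
    }
  }

  # collapse to classes and eliminate the last class via the charge constraint
  M <- sapply(seq_len(nc), function(c) rowSums(basis[, classes == c, drop = FALSE]))
  M <- matrix(M, nrow = nrow(pts))
  counts <- tabulate(classes, nc)
  y <- phi_ref - offset
  if (nc == 1L) {
    qc <- Q_total / counts
    resid <- y - M %*% qc
    charges <- qc[classes]
  } else {
    # q_nc = (Q_total - sum_{c<nc} n_c q_c)/n_nc
    Mred <- M[, -nc, drop = FALSE] -
      M[, nc, drop = FALSE] %*% t(counts[-nc] / counts[nc])
    yred <- y - M[, nc] * Q_total / counts[nc]
    qr_ <- qr(Mred)
    if (qr_$rank < ncol(Mred)) {
      sv <- svd(Mred, nu = 0, nv = 0)$d
      stop(sprintf(
        "rank-deficient ESP design (rank %d of %d, condition number %.3e)",
        qr_$rank, ncol(Mred), max(sv) / max(min(sv), .Machine$double.xmin)))
    }
    qfree <- qr.coef(qr_, yred)
    qlast <- (Q_total - sum(counts[-nc] * qfree)) / counts[nc]
    qc <- c(qfree, qlast)
    resid <- y - M %*% qc
    charges <- qc[classes]
  }
  sv <- svd(M, nu = 0, nv = 0)$d
  list(charges = charges, class_charges = qc,
       rmsd = sqrt(mean(resid^2)),
       condition = max(sv) / max(min(sv), .Machine$double.xmin))
}

.uniform_charges <- function(mol) rep(mol$formal_charge / nrow(mol$atoms),
                                      nrow(mol$atoms))

## ---------------------------------------------------------------------------
## Analytic single-ion models: P, P+G, P+G+G, P+1S, P+1S+2S
## ---------------------------------------------------------------------------

.ion_model_kinds <- list(
  "P" = character(0),
  "P+G" = "gaussian",
  "P+G+G" = c("gaussian", "gaussian"),
  "P+1S" = "slater1s",
  "P+1S+2S" = c("slater1s", "slater2s"))

# radial model potential: point core (charge Q - sum q_k) plus distributed
# carriers; par = (q_1, zeta_1, q_2, zeta_2, ...)
.ion_model_phi <- function(kind, Q, par, r) {
  kinds <- .ion_model_kinds[[kind]]
  qs <- par[seq_along(kinds) * 2 - 1]
  zs <- par[seq_along(kinds) * 2]
  q_core <- Q - sum(qs)
  phi <- KE_COULOMB * q_core / r
  for (k in seq_along(kinds))
    phi <- phi + KE_COULOMB * qs[k] *
      .shape_dispatch("point", NA_real_, kinds[k], zs[k], r)
  phi
}

#' Fit an analytic core-plus-valence model to a radial ESP curve
#'
#' Nonlinear least squares for monatomic-ion ESP models built from a point
#' core and one or two Gaussian or Slater distributed charges; the core charge
#' is eliminated through the total-charge constraint. Eight deterministic
#' multistarts guard against local minima; ties are broken by the lowest
#' first exponent. Points with `r = 0` are excluded (every model contains a
#' point core).
#'
#' @param reference data frame with columns `r` (Angstrom) and `phi`
#'   (kJ/(mol e)), or an `esp_grid` with values (radial provenance)
#' @param kind one of `"P"`, `"P+G"`, `"P+G+G"`, `"P+1S"`, `"P+1S+2S"`
#' @param Q ion charge (e)
#' @param range fit range `c(r_lo, r_hi)` in Angstrom
#' @return an `ion_model_fit`: fitted `charges` (including the core),
#'   `zetas`, `rmsd` over the fit range, `kind`, `range`
#' @export
fit_ion_model <- function(reference, kind, Q, range = c(0, 4.5)) {
  if (inherits(reference, "esp_grid")) {
    r <- sqrt(rowSums(reference$points^2))
    reference <- data.frame(r = r, phi = reference$values)
  }
  stopifnot(all(c("r", "phi") %in% names(reference)),
            kind %in% names(.ion_model_kinds))
  sel <- reference$r >= range[1] & reference$r <= range[2] & reference$r > 0
  if (!any(sel)) stop("reference does not cover the fit range")
  r <- reference$r[sel]; phi <- reference$phi[sel]
  kinds <- .ion_model_kinds[[kind]]
  np <- 2L * length(kinds)

  if (np == 0L) {
    resid <- phi - KE_COULOMB * Q / r
    return(structure(list(kind = kind, charges = Q, zetas = numeric(0),
                          range = range, rmsd = sqrt(mean(resid^2))),
                     class = "ion_model_fit"))
  }

  # deterministic multistarts: negative valence charges (the electron cloud)
  # of plausible magnitude, and a spread of exponents
  sgn <- -1
  qmag <- abs(Q) + c(1, 8)
  zgrid <- c(0.8, 1.6, 3.2, 6.4)
  starts <- list()
  for (qm in qmag) for (z0 in zgrid) {
    p <- c(sgn * qm, z0)
    if (length(kinds) == 2) p <- c(p, sgn * qm / 2, z0 * 2)
    starts[[length(starts) + 1L]] <- p
  }
  starts <- starts[1:8]

  fits <- lapply(starts, function(p0) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) {
          zs <- p[seq_along(kinds) * 2]
          if (any(zs <= 0)) return(rep(1e8, length(r)))
          .ion_model_phi(kind, Q, p, r) - phi
        },
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-13)),
      error = function(e) NULL)
    res
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("no multistart converged in ion-model fit (", length(starts), " starts)")
  }
  fits <- fits[ok]
  rms <- vapply(fits, function(f) sqrt(mean(f$fvec^2)), numeric(1))
  z1 <- vapply(fits, function(f) f$par[2], numeric(1))
  best <- order(round(rms, 12), z1)[1]
  p <- fits[[best]]$par
  qs <- p[seq_along(kinds) * 2 - 1]
  zs <- p[seq_along(kinds) * 2]
  structure(list(kind = kind,
                 charges = c(core = Q - sum(qs), qs),
                 zetas = zs, range = range,
                 rmsd = rms[best]),
            class = "ion_model_fit")
}

#' @export
print.ion_model_fit <- function(x, ...) {
  cat(sprintf("<ion_model_fit> %s: core %+.4f e", x$kind, x$charges[1]))
  if (length(x$zetas))
    cat(sprintf("; valence q = (%s) e, zeta = (%s) 1/A",
                paste(sprintf("%+.4f", x$charges[-1]), collapse = ", "),
                paste(sprintf("%.4f", x$zetas), collapse = ", ")))
  cat(sprintf("; RMSD %.3e kJ/(mol e) on [%g, %g] A\n",
              x$rmsd, x$range[1], x$range[2]))
  invisible(x)
}
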