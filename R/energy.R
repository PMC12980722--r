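#' Construct a dimer frame
#'
#' A pair of site systems at fixed geometry. `r_min` is the shortest
#' intermolecular atom-atom (parent) distance.
#'
#' @param sys_a,sys_b `site_system` objects
#' @param frame_id,dimer_id identifiers
#' @param split `"train"` or `"test"`
#' @return an object of class `dimer_frame`
#' @export
dimer_frame <- function(sys_a, sys_b, frame_id = "f0", dimer_id = "d0",
                        split = "train") {
  stopifnot(inherits(sys_a, "site_system"), inherits(sys_b, "site_system"),
            split %in% c("train", "test"))
  xa <- coords(sys_a$molecule); xb <- coords(sys_b$molecule)
  d <- .cross_dist(xa, xb)
  r_min <- min(d)
  if (!is.finite(r_min) || r_min <= 0)
    stop("degenerate dimer geometry (r_min = ", r_min, ")")
  structure(list(sys_a = sys_a, sys_b = sys_b, frame_id = frame_id,
                 dimer_id = dimer_id, r_min = r_min, split = split),
            class = "dimer_frame")
}

# all pairwise distances between two coordinate sets
.cross_dist <- function(xa, xb) {
  sqrt(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb))
}

.site_xyz <- function(sys) as.matrix(sys$sites[, c("x", "y", "z")])

#' Intermolecular electrostatic energy of a dimer frame
#'
#' Sum of pair energies over all intermolecular site pairs, with shells at
#' their current (by default rest) positions. Intramolecular pairs are
#' excluded entirely.
#'
#' @param frame a `dimer_frame`
#' @return energy in kJ/mol
#' @export
electrostatic_energy <- function(frame) {
  stopifnot(inherits(frame, "dimer_frame"))
  sa <- frame$sys_a$sites; sb <- frame$sys_b$sites
  d <- .cross_dist(.site_xyz(frame$sys_a), .site_xyz(frame$sys_b))
  na <- nrow(sa); nb <- nrow(sb)
  ia <- rep(seq_len(na), nb); ib <- rep(seq_len(nb), each = na)
  r <- as.vector(d)
  pp <- sa$kind[ia] == "point" & sb$kind[ib] == "point"
  bad <- pp & r < 1e-12
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("coincident point-point intermolecular pair (site %d of %s, site %d of %s)",
                 ia[k], frame$sys_a$molecule$name, ib[k], frame$sys_b$molecule$name))
  }
  f <- .shape_vec(sa$kind[ia], sa$zeta[ia], sb$kind[ib], sb$zeta[ib], r)
  sum(KE_COULOMB * sa$q[ia] * sb$q[ib] * f)
}

#' Attractive Born-Mayer induction-correction energy
#'
#' `sum over intermolecular atom pairs of -A_ic exp(-b_ic r)`, evaluated
#' between atom (core parent) positions. Strictly non-positive and
#' monotonically increasing towards zero with distance.
#'
#' @param frame a `dimer_frame`
#' @param A_ic amplitude (kJ/mol, >= 0)
#' @param b_ic inverse range (1/Angstrom, > 0)
#' @return energy in kJ/mol
#' @export
induction_correction <- function(frame, A_ic, b_ic) {
  stopifnot(A_ic >= 0, b_ic > 0)
  if (A_ic == 0) return(0)
  d <- .cross_dist(coords(frame$sys_a$molecule), coords(frame$sys_b$molecule))
  -A_ic * sum(exp(-b_ic * d))
}

#' Relax polarizable shells of a dimer frame
#'
#' Minimises the total energy (intermolecular electrostatics plus harmonic
#' shell springs) over the shell displacements of both monomers (mutual
#' polarization; set `mutual = FALSE` to relax only the first monomer's
#' shells). Shells feel only intermolecular fields plus their own spring;
#' intramolecular electrostatics is excluded throughout. The induction energy
#' is the energy lowering relative to shells at rest, plus the Born-Mayer
#' induction-correction term when the model requests it.
#'
#' @param frame a `dimer_frame` whose systems contain at least one shell
#' @param mutual relax shells of both monomers (default) or only of `sys_a`
#' @param gtol convergence threshold on the maximum gradient component
#'   (kJ/mol/Angstrom)
#' @param max_iter iteration budget
#' @return list with `frame` (relaxed shell positions), `e_induction`
#'   (kJ/mol), `e_elec_rest`, `displacements` and the final gradient norm
#' @export
relax_shells <- function(frame, mutual = TRUE, gtol = 1e-6, max_iter = 10000) {
  stopifnot(inherits(frame, "dimer_frame"))
  sa <- frame$sys_a; sb <- frame$sys_b
  sha <- which(sa$sites$role == "shell")
  shb <- if (mutual) which(sb$sites$role == "shell") else integer(0)
  nsh <- length(sha) + length(shb)
  if (nsh == 0L) stop("no shells present in the frame")
  ka <- sa$springs[sha]; kb <- sb$springs[shb]
  if (any(c(ka, kb) <= 0)) stop("shell spring constants must be positive")

  core <- .relax_core(
    xa0 = .site_xyz(sa), xb0 = .site_xyz(sb),
    kin_a = sa$sites$kind, za = sa$sites$zeta, qa = sa$sites$q,
    kin_b = sb$sites$kind, zb = sb$sites$zeta, qb = sb$sites$q,
    sha = sha, shb = shb, springs = c(ka, kb),
    gtol = gtol, max_iter = max_iter)
  dm <- core$dm
  disp <- core$disp
  opt <- list(value = core$e_min)
  e_rest <- core$e_rest
  xa0 <- .site_xyz(sa); xb0 <- .site_xyz(sb)
  # write back relaxed positions
  if (length(sha)) {
    sa$sites[sha, c("x", "y", "z")] <- xa0[sha, , drop = FALSE] +
      dm[seq_along(sha), , drop = FALSE]
  }
  if (length(shb)) {
    sb$sites[shb, c("x", "y", "z")] <- xb0[shb, , drop = FALSE] +
      dm[length(sha) + seq_along(shb), , drop = FALSE]
  }
  out <- frame; out$sys_a <- sa; out$sys_b <- sb
  e_ind <- opt$value - e_rest
  model <- frame$sys_a$model
  if (isTRUE(model$induction_correction)) {
    ffg <- attr(frame, "ff_global")
    if (!is.null(ffg))
      e_ind <- e_ind + induction_correction(frame, ffg$A_ic, ffg$b_ic)
  }
  list(frame = out, e_induction = e_ind, e_elec_rest = e_rest,
       displacements = disp, grad_norm = core$grad_max)
}

# array-level shell relaxation shared by relax_shells and the trainer's
# compiled evaluator: minimises intermolecular electrostatics + springs over
# shell displacements, L-BFGS-B with analytic gradient. For the point /
# Gaussian family every pair kernel collapses to erf(zeta_eff r)/r (with
# zeta_eff = Inf for point-point), giving a fully vectorised fast path.
.relax_core <- function(xa0, xb0, kin_a, za, qa, kin_b, zb, qb,
                        sha, shb, springs, gtol = 1e-6, max_iter = 10000) {
  na <- nrow(xa0); nb <- nrow(xb0)
  nsh <- length(sha) + length(shb)
  ia <- rep(seq_len(na), nb); ib <- rep(seq_len(nb), each = na)

  place <- function(d) {
    dm <- matrix(d, ncol = 3)
    xa <- xa0; xb <- xb0
    if (length(sha)) xa[sha, ] <- xa0[sha, , drop = FALSE] + dm[seq_along(sha), , drop = FALSE]
    if (length(shb)) xb[shb, ] <- xb0[shb, , drop = FALSE] + dm[length(sha) + seq_along(shb), , drop = FALSE]
    list(xa = xa, xb = xb, dm = dm)
  }
  fast_pg <- all(kin_a %in% c("point", "gaussian")) &&
    all(kin_b %in% c("point", "gaussian"))
  if (fast_pg) {
    za_ <- ifelse(kin_a == "point", Inf, za)[ia]
    zb_ <- ifelse(kin_b == "point", Inf, zb)[ib]
    zeff <- ifelse(is.infinite(za_), zb_,
                   ifelse(is.infinite(zb_), za_, za_ * zb_ / sqrt(za_^2 + zb_^2)))
    qq <- KE_COULOMB * qa[ia] * qb[ib]
    pair_geom <- function(p) {
      dx1 <- p$xb[ib, 1] - p$xa[ia, 1]
      dx2 <- p$xb[ib, 2] - p$xa[ia, 2]
      dx3 <- p$xb[ib, 3] - p$xa[ia, 3]
      list(dx1 = dx1, dx2 = dx2, dx3 = dx3,
           r = sqrt(dx1^2 + dx2^2 + dx3^2))
    }
    eval_energy <- function(d) {
      p <- place(d)
      g <- pair_geom(p)
      t <- zeff * g$r
      f <- ifelse(is.finite(t), erf(t), 1) / g$r
      sum(qq * f) + 0.5 * sum(springs * rowSums(p$dm^2))
    }
    eval_grad <- function(d) {
      p <- place(d)
      g <- pair_geom(p)
      t <- zeff * g$r
      fin <- is.finite(t)
      ef <- ifelse(fin, erf(t), 1)
      gaussterm <- ifelse(fin, (2 * zeff / sqrt(pi)) * exp(-t^2), 0)
      fp <- gaussterm / g$r - ef / g$r^2
      w <- qq * fp / g$r
      ga <- cbind(rowsum(w * g$dx1, ia), rowsum(w * g$dx2, ia),
                  rowsum(w * g$dx3, ia))
      gb <- cbind(rowsum(w * g$dx1, ib), rowsum(w * g$dx2, ib),
                  rowsum(w * g$dx3, ib))
      gm <- rbind(-ga[sha, , drop = FALSE], gb[shb, , drop = FALSE])
      as.vector(gm + springs * p$dm)
    }
  } else {
    eval_energy <- function(d) {
      p <- place(d)
      r <- as.vector(.cross_dist(p$xa, p$xb))
      f <- .shape_vec(kin_a[ia], za[ia], kin_b[ib], zb[ib], r)
      sum(KE_COULOMB * qa[ia] * qb[ib] * f) + 0.5 * sum(springs * rowSums(p$dm^2))
    }
    eval_grad <- function(d) {
      p <- place(d)
      g <- matrix(0, nsh, 3)
      for (s in seq_along(sha)) {
        i <- sha[s]
        dx <- t(p$xb) - p$xa[i, ]      # 3 x nb
        r <- sqrt(colSums(dx^2))
        fp <- vapply(seq_len(nb), function(j)
          .shape_deriv(kin_a[i], za[i], kin_b[j], zb[j], r[j]), numeric(1))
        w <- KE_COULOMB * qa[i] * qb * fp / r
        g[s, ] <- -as.vector(dx %*% w)
      }
      for (s in seq_along(shb)) {
        j <- shb[s]
        dx <- t(p$xa) - p$xb[j, ]      # 3 x na
        r <- sqrt(colSums(dx^2))
        fp <- vapply(seq_len(na), function(i)
          .shape_deriv(kin_a[i], za[i], kin_b[j], zb[j], r[i]), numeric(1))
        w <- KE_COULOMB * qb[j] * qa * fp / r
        g[length(sha) + s, ] <- -as.vector(dx %*% w)
      }
      as.vector(g + springs * p$dm)
    }
  }

  e_rest <- eval_energy(rep(0, 3 * nsh))
  opt <- stats::optim(rep(0, 3 * nsh), eval_energy, eval_grad,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e1, pgtol = 0))
  # quasi-Newton leaves the gradient at the resolution limit of the energy;
  # a spring-preconditioned fixed-point polish (the springs dominate the
  # curvature) contracts it below gtol
  k3 <- rep(springs, 3)
  par <- opt$par
  gfin <- eval_grad(par)
  polish <- 0L
  while (max(abs(gfin)) > gtol && polish < 200L) {
    polish <- polish + 1L
    par <- par - gfin / k3
    gfin <- eval_grad(par)
  }
  if (eval_energy(par) <= opt$value + 1e-9) opt <- list(par = par, value = eval_energy(par))
  else gfin <- eval_grad(opt$par)
  if (max(abs(gfin)) > gtol)
    stop(sprintf("shell relaxation not converged: max |gradient| = %.3e kJ/mol/A",
                 max(abs(gfin))))
  dm <- matrix(opt$par, ncol = 3)
  disp <- sqrt(rowSums(dm^2))
  if (any(disp > 1))
    stop(sprintf("polarization catastrophe: shell displacement %.3f A > 1 A",
                 max(disp)))
  list(dm = dm, disp = disp, e_rest = e_rest, e_min = opt$value,
       grad_max = max(abs(gfin)))
}

#' Evaluate a force field against reference dimer energy components
#'
#' Computes model electrostatic (and, for polarizable models, induction)
#' energies for every frame of a reference dataset and reports RMSD and mean
#' signed error (model - reference) per dimer pair and overall, separately
#' for the train and test splits. The component `"Elec+Induc"` compares the
#' sums of the two energies. Fixed external charge tables (e.g. published
#' point-charge sets) can be evaluated by passing `charges`.
#'
#' @param ff a `force_field`
#' @param model a `model_definition`
#' @param data a `ref_dataset` (see [reference_components()])
#' @param components character vector from `"Elec"`, `"Induc"`, `"Elec+Induc"`
#' @param charges optional named list (by molecule name) of fixed atomic
#'   charge vectors, bypassing SQE
#' @return an `eval_report` data frame with columns `dimer_id`, `split`,
#'   `component`, `n`, `rmsd`, `mse` (overall rows have `dimer_id = "all"`)
#' @export
evaluate_ff <- function(ff, model, data, components = "Elec", charges = NULL) {
  pred <- predict_components(ff, model, data,
                             need_induc = any(components %in% c("Induc", "Elec+Induc")),
                             charges = charges)
  comp <- data$components
  stopifnot(nrow(comp) == nrow(pred))
  rows <- list()
  add <- function(dimer, split, component, dm, dr) {
    if (!length(dm)) return()
    e <- dm - dr
    rows[[length(rows) + 1L]] <<- data.frame(
      dimer_id = dimer, split = split, component = component,
      n = length(e), rmsd = sqrt(mean(e^2)), mse = mean(e))
  }
  for (cc in components) {
    dm <- switch(cc,
      "Elec" = pred$elec,
      "Induc" = pred$induc,
      "Elec+Induc" = pred$elec + pred$induc,
      stop("unknown component '", cc, "'"))
    dr <- switch(cc,
      "Elec" = comp$E_elec_kJmol,
      "Induc" = comp$E_induc_kJmol,
      "Elec+Induc" = comp$E_elec_kJmol + comp$E_induc_kJmol)
    if (all(is.na(dr))) stop("reference component '", cc, "' is empty")
    for (sp in unique(comp$split)) {
      si <- comp$split == sp
      for (dd in unique(comp$dimer_id[si])) {
        di <- si & comp$dimer_id == dd
        add(dd, sp, cc, dm[di], dr[di])
      }
      add("all", sp, cc, dm[si], dr[si])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", class(out))
  out
}

# model energies for every frame of a dataset; the workhorse behind both
# evaluate_ff and the trainer fitness (which uses the compiled fast path)
predict_components <- function(ff, model, data, need_induc = FALSE,
                               charges = NULL) {
  mols <- data$molecules
  qs <- lapply(names(mols), function(nm) {
    if (!is.null(charges) && !is.null(charges[[nm]])) charges[[nm]]
    else sqe_charges(mols[[nm]], ff)
  })
  names(qs) <- names(mols)
  nfr <- length(data$frames)
  elec <- numeric(nfr); induc <- numeric(nfr)
  polar <- model$shell
  for (k in seq_len(nfr)) {
    fr <- data$frames[[k]]
    ma <- set_coords(mols[[fr$mol_a]], fr$xyz_a)
    mb <- set_coords(mols[[fr$mol_b]], fr$xyz_b)
    sa <- build_site_system(ma, model, ff, qs[[fr$mol_a]])
    sb <- build_site_system(mb, model, ff, qs[[fr$mol_b]])
    dfr <- dimer_frame(sa, sb, fr$frame_id, fr$dimer_id, fr$split)
    attr(dfr, "ff_global") <- ff$global
    elec[k] <- electrostatic_energy(dfr)
    if (need_induc && polar) {
      induc[k] <- relax_shells(dfr)$e_induction
    } else if (need_induc && isTRUE(model$induction_correction)) {
      induc[k] <- induction_correction(dfr, ff$global$A_ic, ff$global$b_ic)
    }
  }
  data.frame(frame_id = vapply(data$frames, `[[`, "", "frame_id"),
             elec = elec, induc = induc)
}
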