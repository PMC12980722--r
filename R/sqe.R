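#' Assemble the split-charge equilibration (SQE) system of a molecule
#'
#' SQE distributes a molecule's formal charge over its atoms by minimising a
#' quadratic energy in the bond "split charges" p:
#' \deqn{E(p) = \sum_i [\chi_i q_i + \tfrac12 \eta_i q_i^2]
#'            + \sum_b [\Delta\chi_b p_b + \tfrac12 \Delta\eta_b p_b^2],
#'       \quad q = q_{ref} + T p}
#' where T is the atom-by-bond incidence matrix (+1 at each bond's canonical
#' head, -1 at its tail). The reference charges distribute the formal charge
#' uniformly; any charge flow is then carried by the bond variables, so total
#' charge is conserved exactly for every parameter set. Charges depend only on
#' topology and parameters, not on geometry, and so are conformation
#' independent.
#'
#' Bond direction is canonicalised lexicographically by atom type (head = the
#' smaller type string, ties broken by atom index); `delta_chi` is stored for
#' the canonical direction and flips sign on reversal.
#'
#' @param mol a `molecule`
#' @param ff a `force_field` supplying `chi`, `eta` per atom type and
#'   `delta_chi`, `delta_eta` per bond type
#' @return an object of class `sqe_system` with elements `T` (incidence),
#'   `q_ref`, `A` (bond-space quadratic form, V/e) and `b` (linear term, V)
#' @export
sqe_assemble <- function(mol, ff) {
  stopifnot(inherits(mol, "molecule"), inherits(ff, "force_field"))
  n <- nrow(mol$atoms)
  m <- nrow(mol$bonds)
  types <- mol$atoms$atom_type
  at <- ff$atom_types[match(types, ff$atom_types$type), ]
  if (anyNA(at$chi))
    stop("atom type '", types[which(is.na(at$chi))[1]], "' not in force field")
  chi <- at$chi; eta <- at$eta
  if (any(eta <= 0)) stop("eta must be > 0 (positive-definite SQE)")

  Tm <- matrix(0, n, m)
  delta_chi <- numeric(m)
  delta_eta <- numeric(m)
  for (k in seq_len(m)) {
    i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
    ti <- types[i]; tj <- types[j]
    # canonical head: lexicographically smaller atom type, then lower index
    if (tj < ti || (tj == ti && j < i)) { tmp <- i; i <- j; tmp2 <- ti; ti <- tj; tj <- tmp2; j <- tmp }
    Tm[i, k] <- 1; Tm[j, k] <- -1
    bt <- .ff_bond(ff, ti, tj)
    if (bt$delta_eta <= 0) stop("delta_eta must be > 0 (positive-definite SQE)")
    delta_chi[k] <- bt$delta_chi
    delta_eta[k] <- bt$delta_eta
  }
  q_ref <- rep(mol$formal_charge / n, n)
  A <- if (m) crossprod(Tm, Tm * eta) + diag(delta_eta, m) else
    matrix(0, 0, 0)
  b <- if (m) as.vector(crossprod(Tm, chi + eta * q_ref)) + delta_chi else
    numeric(0)
  structure(list(T = Tm, q_ref = q_ref, A = A, b = b,
                 molecule = mol),
            class = "sqe_system")
}

#' Solve an SQE system for atomic charges
#'
#' Minimises the SQE quadratic form in bond space; the minimiser is unique
#' because the quadratic form is positive definite whenever all `eta` and
#' `delta_eta` are positive. Total charge equals the formal charge exactly,
#' and topologically equivalent atoms receive equal charges.
#'
#' @param sys an `sqe_system` from [sqe_assemble()]
#' @return numeric vector of per-atom charges in e
#' @export
#' @examples
#' ff <- force_field(
#'   atom_types = data.frame(type = c("A", "B"), chi = c(5, 8), eta = c(10, 10)),
#'   bond_types = data.frame(type1 = "A", type2 = "B", delta_chi = 0, delta_eta = 4))
#' mol <- molecule("AB", data.frame(element = c("H", "F"), atom_type = c("A", "B"),
#'                                  x = c(0, 1), y = 0, z = 0))
#' mol$bonds <- matrix(c(1L, 2L), ncol = 2)
#' solve_charges(sqe_assemble(mol, ff))  # +0.125, -0.125
solve_charges <- function(sys) {
  stopifnot(inherits(sys, "sqe_system"))
  m <- ncol(sys$T)
  if (m == 0L) return(sys$q_ref)
  ch <- tryCatch(chol(sys$A), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(sys$A, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("SQE quadratic form is not positive definite (min eigenvalue %.3e)", ev))
  }
  p <- backsolve(ch, backsolve(ch, -sys$b, transpose = TRUE))
  as.vector(sys$q_ref + sys$T %*% p)
}

#' SQE energy of a bond-charge vector (V e units)
#'
#' Mostly a testing aid: evaluates the SQE objective at an arbitrary
#' split-charge vector `p`.
#'
#' @param sys an `sqe_system`
#' @param p bond split charges (e)
#' @return energy in V e (multiply by `EV_TO_KJMOL` for kJ/mol)
#' @export
sqe_energy <- function(sys, p) {
  stopifnot(length(p) == ncol(sys$T))
  # E(p) - E-independent reference term: b.p + 0.5 p.A.p
  sum(sys$b * p) + 0.5 * sum(p * (sys$A %*% p))
}

#' Atomic charges of a molecule under a force field
#'
#' Convenience wrapper: assemble and solve SQE in one call.
#'
#' @inheritParams sqe_assemble
#' @return per-atom charges in e
#' @export
sqe_charges <- function(mol, ff) solve_charges(sqe_assemble(mol, ff))
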