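#' Construct a molecule
#'
#' A molecule is an ordered set of atoms with coordinates, a bond list and an
#' integer formal charge. Bonds are topology only; no bonded energy terms
#' exist in this package.
#'
#' @param name molecule name
#' @param atoms data frame with columns `element`, `atom_type`, `x`, `y`, `z`
#'   (Angstrom) and optionally `vdw_radius`; missing radii are filled from the
#'   Bondi table via [vdw_radius()]
#' @param bonds two-column matrix (or empty) of 1-based atom index pairs
#' @param formal_charge integer total charge in e
#' @return an object of class `molecule`
#' @export
molecule <- function(name, atoms, bonds = matrix(integer(), ncol = 2),
                     formal_charge = 0L) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L,
            all(c("element", "atom_type", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- vdw_radius(atoms$element)
  if (any(atoms$vdw_radius <= 0)) stop("vdw_radius must be positive")
  if (abs(formal_charge - round(formal_charge)) > 1e-9)
    stop("formal_charge must be an integer")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L | bonds > n)) stop("bond indices out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("bond connects an atom to itself")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  mol <- structure(list(name = name, atoms = atoms, bonds = bonds,
                        formal_charge = as.integer(round(formal_charge))),
                   class = "molecule")
  if (n > 1L && !.connected(n, bonds))
    stop("bond graph of polyatomic molecule '", name, "' is not connected")
  mol
}

# breadth-first connectivity check
.connected <- function(n, bonds) {
  if (n == 1L) return(TRUE)
  if (nrow(bonds) == 0L) return(FALSE)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds, charge %+d e\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$formal_charge))
  invisible(x)
}

#' Coordinates of a molecule as a matrix
#' @param mol a `molecule`
#' @return n x 3 numeric matrix (Angstrom)
#' @export
coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' Replace the coordinates of a molecule
#' @param mol a `molecule`
#' @param xyz n x 3 matrix
#' @return the molecule with updated positions
#' @export
set_coords <- function(mol, xyz) {
  stopifnot(nrow(xyz) == nrow(mol$atoms), ncol(xyz) == 3)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

.water_like <- function(mol) {
  nrow(mol$atoms) == 3L &&
    sort(mol$atoms$element) [1] == "H" &&
    identical(sort(mol$atoms$element), c("H", "H", "O")) &&
    nrow(mol$bonds) == 2L
}

#' Model definition: which charge carriers a model places on a molecule
#'
#' Named presets follow the standard catalogue: `PC`, `GC`, `SC` are bare
#' atomic charges (point / Gaussian / Slater); `PC+GV3x`, `PC+SV3x`,
#' `PC+GV4x`, `PC+SV4x`, `PC+GV4`, `PC+SV4` add a distributed virtual site on
#' every atom (3P or 4P water); `PC+GS4` replaces the static virtual sites by
#' mobile polarizable shells and enables the attractive Born-Mayer induction
#' correction.
#'
#' @param name preset name, or an arbitrary label when the remaining arguments
#'   are given explicitly
#' @param core_kind distribution kind of the atomic cores
#' @param vsite_kind optional distribution kind for atom-centred virtual
#'   sites; mutually exclusive with `shell`
#' @param shell logical; mobile polarizable shells instead of static vsites
#' @param shell_kind distribution kind carried by shells (default Gaussian)
#' @param water_sites `"3P"` or `"4P"`; with `"4P"` the charge carriers of a
#'   water oxygen are relocated to a massless site on the H-O-H bisector at
#'   distance `r_OM` from the oxygen, on the hydrogen side
#' @param induction_correction logical; evaluate the attractive
#'   `-A_ic exp(-b_ic r)` term between intermolecular atom pairs
#' @return an object of class `model_definition`
#' @export
model_definition <- function(name,
                             core_kind = NULL, vsite_kind = NULL,
                             shell = NULL, shell_kind = "gaussian",
                             water_sites = NULL,
                             induction_correction = NULL) {
  presets <- list(
    "PC"      = list("point",    NULL,       FALSE, "3P", FALSE),
    "GC"      = list("gaussian", NULL,       FALSE, "3P", FALSE),
    "SC"      = list("slater1s", NULL,       FALSE, "3P", FALSE),
    "PC+GV3x" = list("point",    "gaussian", FALSE, "3P", FALSE),
    "PC+SV3x" = list("point",    "slater1s", FALSE, "3P", FALSE),
    "PC+GV4x" = list("point",    "gaussian", FALSE, "4P", FALSE),
    "PC+SV4x" = list("point",    "slater1s", FALSE, "4P", FALSE),
    "PC+GV4"  = list("point",    "gaussian", FALSE, "4P", FALSE),
    "PC+SV4"  = list("point",    "slater1s", FALSE, "4P", FALSE),
    "PC+GS4"  = list("point",    NULL,       TRUE,  "4P", TRUE)
  )
  if (name %in% names(presets)) {
    p <- presets[[name]]
    core_kind <- core_kind %||% p[[1]]
    vsite_kind <- vsite_kind %||% p[[2]]
    shell <- shell %||% p[[3]]
    water_sites <- water_sites %||% p[[4]]
    induction_correction <- induction_correction %||% p[[5]]
  } else {
    core_kind <- core_kind %||% "point"
    shell <- shell %||% FALSE
    water_sites <- water_sites %||% "3P"
    induction_correction <- induction_correction %||% FALSE
  }
  stopifnot(core_kind %in% names(.kind_order),
            water_sites %in% c("3P", "4P"))
  if (shell && !is.null(vsite_kind))
    stop("shells replace static virtual sites; 'shell' and 'vsite_kind' are mutually exclusive")
  if (!is.null(vsite_kind)) stopifnot(vsite_kind %in% names(.kind_order))
  structure(list(name = name, core_kind = core_kind, vsite_kind = vsite_kind,
                 shell = shell, shell_kind = shell_kind,
                 water_sites = water_sites,
                 induction_correction = induction_correction),
            class = "model_definition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_definition <- function(x, ...) {
  cat(sprintf("<model_definition> %s: core=%s vsite=%s shell=%s water=%s ic=%s\n",
              x$name, x$core_kind, x$vsite_kind %||% "-",
              if (x$shell) x$shell_kind else "-", x$water_sites,
              x$induction_correction))
  invisible(x)
}

#' Construct a force field parameter table
#'
#' Holds, per atom type: SQE electronegativity `chi` (V), hardness `eta`
#' (V/e), virtual-site/shell charge `q_V` (e) and width `zeta_V` (1/A), core
#' distribution width `zeta` (1/A, used when the model's cores are
#' distributed), and polarizability volume `alpha` (A^3). Per bond type
#' (canonical lexicographic atom-type pair): bond electronegativity difference
#' `delta_chi` (V, antisymmetric under pair reversal) and bond hardness
#' `delta_eta` (V/e, > 0). Global parameters: the induction-correction
#' amplitude `A_ic` (kJ/mol) and range `b_ic` (1/A), and the water
#' oxygen-to-bisector-site distance `r_OM` (A).
#'
#' @param atom_types data frame with columns `type`, `chi`, `eta` and
#'   optionally `q_V`, `zeta_V`, `zeta`, `alpha` (defaults 0 / 1 / 1 / 0)
#' @param bond_types data frame with columns `type1`, `type2`, `delta_chi`,
#'   `delta_eta`; rows are canonicalised so `type1 <= type2`, flipping the
#'   sign of `delta_chi` when the input order is reversed
#' @param A_ic,b_ic,r_OM global parameters (see above)
#' @return an object of class `force_field`
#' @export
force_field <- function(atom_types, bond_types = NULL,
                        A_ic = 0, b_ic = 1, r_OM = 0) {
  stopifnot(is.data.frame(atom_types),
            all(c("type", "chi", "eta") %in% names(atom_types)))
  for (col in c("q_V", "zeta_V", "zeta", "alpha")) {
    if (is.null(atom_types[[col]]))
      atom_types[[col]] <- switch(col, q_V = 0, zeta_V = 1, zeta = 1, alpha = 0)
  }
  if (anyDuplicated(atom_types$type)) stop("duplicate atom type")
  if (any(atom_types$eta <= 0)) stop("eta must be > 0 for every atom type")
  if (any(atom_types$zeta_V <= 0) || any(atom_types$zeta <= 0))
    stop("distribution widths must be > 0")
  if (any(atom_types$alpha < 0)) stop("alpha must be >= 0")
  if (is.null(bond_types))
    bond_types <- data.frame(type1 = character(), type2 = character(),
                             delta_chi = numeric(), delta_eta = numeric())
  stopifnot(all(c("type1", "type2", "delta_chi", "delta_eta") %in% names(bond_types)))
  if (nrow(bond_types)) {
    flip <- bond_types$type1 > bond_types$type2
    if (any(flip)) {
      tmp <- bond_types$type1[flip]
      bond_types$type1[flip] <- bond_types$type2[flip]
      bond_types$type2[flip] <- tmp
      bond_types$delta_chi[flip] <- -bond_types$delta_chi[flip]
    }
    if (any(bond_types$delta_eta <= 0)) stop("delta_eta must be > 0")
    same <- bond_types$type1 == bond_types$type2
    if (any(same & bond_types$delta_chi != 0))
      stop("delta_chi must vanish for homonuclear bond types")
    if (anyDuplicated(paste(bond_types$type1, bond_types$type2)))
      stop("duplicate bond type")
  }
  if (A_ic < 0) stop("A_ic must be >= 0")
  if (b_ic <= 0) stop("b_ic must be > 0")
  if (r_OM < 0) stop("r_OM must be >= 0")
  structure(list(atom_types = atom_types, bond_types = bond_types,
                 global = list(A_ic = A_ic, b_ic = b_ic, r_OM = r_OM)),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("<force_field> %d atom types, %d bond types; A_ic=%g b_ic=%g r_OM=%g\n",
              nrow(x$atom_types), nrow(x$bond_types),
              x$global$A_ic, x$global$b_ic, x$global$r_OM))
  invisible(x)
}

# row of the atom-type table, with a helpful error
.ff_atom <- function(ff, type) {
  i <- match(type, ff$atom_types$type)
  if (is.na(i)) stop("atom type '", type, "' not in force field")
  ff$atom_types[i, ]
}

.ff_bond <- function(ff, type_i, type_j) {
  t1 <- min(type_i, type_j); t2 <- max(type_i, type_j)
  k <- which(ff$bond_types$type1 == t1 & ff$bond_types$type2 == t2)
  if (!length(k)) stop("bond type '", t1, "-", t2, "' not in force field")
  ff$bond_types[k, ]
}

#' Get or set a force-field parameter by path
#'
#' Paths take the form `"atom.<type>.<field>"` (fields `chi`, `eta`, `q_V`,
#' `zeta_V`, `zeta`, `alpha`), `"bond.<t1>-<t2>.<field>"` (fields `delta_chi`,
#' `delta_eta`; the pair in canonical order) or `"global.<field>"` (`A_ic`,
#' `b_ic`, `r_OM`). Used by the trainer to address trainable parameters.
#'
#' @param ff a `force_field`
#' @param path parameter path string
#' @param value replacement value (for `ff_set`)
#' @return `ff_get` returns the numeric value; `ff_set` the modified force field
#' @export
ff_get <- function(ff, path) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  switch(p[1],
    atom = {
      i <- match(p[2], ff$atom_types$type)
      if (is.na(i) || is.null(ff$atom_types[[p[3]]]))
        stop("cannot resolve parameter path '", path, "'")
      ff$atom_types[[p[3]]][i]
    },
    bond = {
      tt <- strsplit(p[2], "-", fixed = TRUE)[[1]]
      b <- .ff_bond(ff, tt[1], tt[2])
      v <- b[[p[3]]]
      if (is.null(v)) stop("cannot resolve parameter path '", path, "'")
      v
    },
    global = {
      v <- ff$global[[p[2]]]
      if (is.null(v)) stop("cannot resolve parameter path '", path, "'")
      v
    },
    stop("cannot resolve parameter path '", path, "'"))
}

#' @rdname ff_get
#' @export
ff_set <- function(ff, path, value) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  switch(p[1],
    atom = {
      i <- match(p[2], ff$atom_types$type)
      if (is.na(i) || is.null(ff$atom_types[[p[3]]]))
        stop("cannot resolve parameter path '", path, "'")
      ff$atom_types[[p[3]]][i] <- value
    },
    bond = {
      tt <- sort(strsplit(p[2], "-", fixed = TRUE)[[1]])
      k <- which(ff$bond_types$type1 == tt[1] & ff$bond_types$type2 == tt[2])
      if (!length(k) || is.null(ff$bond_types[[p[3]]]))
        stop("cannot resolve parameter path '", path, "'")
      ff$bond_types[[p[3]]][k] <- value
    },
    global = {
      if (is.null(ff$global[[p[2]]]))
        stop("cannot resolve parameter path '", path, "'")
      ff$global[[p[2]]] <- value
    },
    stop("cannot resolve parameter path '", path, "'"))
  ff
}

#' Convert an MBIS valence width to a Slater density exponent
#'
#' The minimal-basis iterative Stockholder valence width `sigma`
#' parameterises the valence density as `exp(-r/sigma)`; the 1S Slater
#' density used here decays as `exp(-2 zeta r)`, hence `zeta = 1/(2 sigma)`.
#'
#' @param sigma valence width in Angstrom (> 0)
#' @return Slater exponent zeta in 1/Angstrom
#' @export
mbis_sigma_to_zeta <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("'sigma' must be > 0")
  1 / (2 * sigma)
}

#' @rdname mbis_sigma_to_zeta
#' @param zeta Slater exponent in 1/Angstrom (> 0)
#' @export
mbis_zeta_to_sigma <- function(zeta) {
  if (any(!is.finite(zeta)) || any(zeta <= 0)) stop("'zeta' must be > 0")
  1 / (2 * zeta)
}

#' Position of the water bisector virtual site
#'
#' The M site of a TIP4P-like water: on the H-O-H bisector, `r_OM` from the
#' oxygen, displaced towards the hydrogens.
#'
#' @param mol a water molecule (3 atoms O, H, H; errors otherwise)
#' @param r_OM oxygen-to-site distance in Angstrom
#' @return 3-vector position
#' @export
water_msite <- function(mol, r_OM) {
  if (!.water_like(mol))
    stop("4P site construction requires a water molecule (O, H, H with two bonds)")
  xyz <- coords(mol)
  io <- which(mol$atoms$element == "O")
  ih <- which(mol$atoms$element == "H")
  u1 <- xyz[ih[1], ] - xyz[io, ]
  u2 <- xyz[ih[2], ] - xyz[io, ]
  bis <- u1 / sqrt(sum(u1^2)) + u2 / sqrt(sum(u2^2))
  bis <- bis / sqrt(sum(bis^2))
  xyz[io, ] + r_OM * bis
}

#' Expand a molecule into an evaluable site system
#'
#' Applies a model definition to a molecule: every atom contributes a core
#' carrying its atomic charge; virtual-site models move a charge `q_V` (of the
#' model's distributed kind, width `zeta_V`) onto a co-located massless site,
#' leaving `q_atom - q_V` on the point core; shell models do the same with a
#' mobile shell tethered by a harmonic spring of constant
#' `k = KE_COULOMB * q_V^2 / alpha` (the Drude identity). For 4P water the
#' oxygen's charge carriers are relocated to the bisector site at distance
#' `r_OM` (taken from the force field). Total charge is conserved exactly.
#'
#' @param mol a `molecule`
#' @param model a `model_definition`
#' @param ff a `force_field`
#' @param atomic_charges per-atom charges in e (e.g. from [solve_charges()]);
#'   must sum to the formal charge within 1e-10
#' @return an object of class `site_system`: a data frame of sites
#'   (`x, y, z, kind, q, zeta, role, parent`), per-site spring constants for
#'   shells, and the originating molecule and model
#' @export
build_site_system <- function(mol, model, ff, atomic_charges) {
  stopifnot(inherits(mol, "molecule"), inherits(model, "model_definition"),
            inherits(ff, "force_field"))
  n <- nrow(mol$atoms)
  stopifnot(length(atomic_charges) == n)
  if (abs(sum(atomic_charges) - mol$formal_charge) > 1e-10)
    stop("atomic charges do not sum to the formal charge")
  xyz <- coords(mol)
  expanded <- !is.null(model$vsite_kind) || model$shell
  carrier_kind <- if (model$shell) model$shell_kind else model$vsite_kind

  rows <- vector("list", n)
  springs <- numeric(0)
  for (i in seq_len(n)) {
    tp <- .ff_atom(ff, mol$atoms$atom_type[i])
    qi <- atomic_charges[i]
    core_zeta <- if (model$core_kind == "point") NA_real_ else tp$zeta
    if (!expanded) {
      rows[[i]] <- data.frame(x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3],
                              kind = model$core_kind, q = qi, zeta = core_zeta,
                              role = "core", parent = i)
    } else {
      if (model$shell && tp$alpha <= 0)
        stop("shell requested for atom type '", tp$type, "' with alpha = 0")
      role2 <- if (model$shell) "shell" else "vsite"
      rows[[i]] <- data.frame(
        x = unname(xyz[i, 1]), y = unname(xyz[i, 2]), z = unname(xyz[i, 3]),
        kind = c(model$core_kind, carrier_kind),
        q = c(qi - tp$q_V, unname(tp$q_V)),
        zeta = c(core_zeta, unname(tp$zeta_V)),
        role = c("core", role2), parent = i, row.names = NULL)
    }
  }
  sites <- do.call(rbind, rows)

  if (model$water_sites == "4P" && .water_like(mol)) {
    m <- water_msite(mol, ff$global$r_OM)
    io <- which(mol$atoms$element == "O")
    relocate <- sites$parent == io
    sites$x[relocate] <- m[1]; sites$y[relocate] <- m[2]; sites$z[relocate] <- m[3]
  }

  k <- rep(NA_real_, nrow(sites))
  if (model$shell) {
    sh <- sites$role == "shell"
    tp_sh <- ff$atom_types[match(mol$atoms$atom_type[sites$parent[sh]],
                                 ff$atom_types$type), ]
    k[sh] <- KE_COULOMB * tp_sh$q_V^2 / tp_sh$alpha
  }

  structure(list(sites = sites, springs = k, molecule = mol, model = model),
            class = "site_system")
}

#' @export
print.site_system <- function(x, ...) {
  cat(sprintf("<site_system> %s/%s: %d sites (%d core, %d vsite, %d shell), total q = %+.6f e\n",
              x$molecule$name, x$model$name, nrow(x$sites),
              sum(x$sites$role == "core"), sum(x$sites$role == "vsite"),
              sum(x$sites$role == "shell"), sum(x$sites$q)))
  invisible(x)
}

#' Total charge of a site system
#' @param sys a `site_system`
#' @return total charge in e
#' @export
total_charge <- function(sys) sum(sys$sites$q)
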