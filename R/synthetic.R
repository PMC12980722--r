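#' Ground-truth generator: molecule library and force field
#'
#' Builds a small library of idealised molecules -- water, a sodium-like
#' cation, a chloride-like anion, a formate-like carboxylate (q = -1) and an
#' ammonium fragment (q = +1) -- together with a fully specified force field
#' whose parameters are drawn deterministically (per seed) inside
#' chemistry-typical ranges. The result serves as the known data-generating
#' model for synthetic reference datasets: electronegativities order H < C <
#' N < O < Cl so that hydrogens stay positive, virtual-site/shell charges are
#' negative, and widths fall in the 1-3 1/Angstrom range typical of valence
#' densities.
#'
#' @param seed integer seed controlling the parameter jitter
#' @param polarizable build a PC+GS4-style polarizable ground truth (shells,
#'   polarizabilities and a Born-Mayer induction correction) instead of the
#'   nonpolarizable PC+GV4 style
#' @return an object of class `ground_truth`: list with `ff`, `model`,
#'   `molecules`
#' @export
make_ground_truth <- function(seed = 1L, polarizable = FALSE) {
  rng <- .local_rng(seed)
  jit <- function(x, frac = 0.08) x * (1 + frac * (2 * rng(length(x)) - 1))

  mols <- list(
    water = .mol_water(),
    cation = .mol_ion("cation", "Na", +1L),
    anion = .mol_ion("anion", "Cl", -1L),
    formate = .mol_formate(),
    ammonium = .mol_ammonium()
  )

  types <- c("HW", "OW", "Na", "Cl", "C", "O", "HC", "HN", "N")
  # electronegativity ordering keeps every hydrogen charge positive (the
  # chemical-sanity rule the trainer penalty enforces) across the jitter
  chi0 <- c(HW = 4.0, OW = 8.5, Na = 2.0, Cl = 9.0, C = 5.5, O = 8.8,
            HC = 1.6, HN = 4.6, N = 7.4)
  eta0 <- c(HW = 14, OW = 11, Na = 20, Cl = 9, C = 10, O = 11, HC = 15,
            HN = 15, N = 11)
  qv0 <- c(HW = -0.45, OW = -1.3, Na = -0.6, Cl = -1.6, C = -0.9, O = -1.4,
           HC = -0.4, HN = -0.4, N = -1.1)
  zv0 <- c(HW = 2.2, OW = 1.7, Na = 2.6, Cl = 1.3, C = 1.8, O = 1.6,
           HC = 2.3, HN = 2.3, N = 1.7)
  # effective (condensed-phase style) polarizabilities; kept stiff enough
  # that the Drude springs resist the fields at vdW contact
  al0 <- c(HW = 0.25, OW = 0.8, Na = 0.2, Cl = 1.5, C = 0.8, O = 0.8,
           HC = 0.3, HN = 0.3, N = 0.8)
  atom_types <- data.frame(
    type = types,
    chi = jit(chi0), eta = jit(eta0),
    q_V = jit(qv0), zeta_V = jit(zv0),
    zeta = jit(zv0 * 1.1), alpha = jit(al0))

  bond_types <- data.frame(
    type1 = c("HW", "C", "C", "HN"),
    type2 = c("OW", "HC", "O", "N"),
    delta_chi = jit(c(-0.5, 3.2, -0.6, -0.5)),
    delta_eta = jit(c(8, 9, 7, 8)))

  ff <- force_field(atom_types, bond_types,
                    A_ic = if (polarizable) jit(60) else 0,
                    b_ic = if (polarizable) jit(2.2) else 1,
                    r_OM = 0.125)
  model <- model_definition(if (polarizable) "PC+GS4" else "PC+GV4")
  structure(list(ff = ff, model = model, molecules = mols),
            class = "ground_truth")
}

# deterministic uniform stream independent of the global RNG
.local_rng <- function(seed) {
  env <- new.env()
  # scramble the seed so neighbouring seeds give unrelated streams
  env$state <- (as.double(seed) * 48271 + 11) %% 2147483647
  if (env$state == 0) env$state <- 1
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      # Park-Miller minimal standard
      env$state <- (16807 * env$state) %% 2147483647
      out[i] <- env$state / 2147483647
    }
    out
  }
}

.mol_water <- function() {
  r_oh <- 0.9572; half <- 104.52 / 2 * pi / 180
  molecule("water", data.frame(
    element = c("O", "H", "H"), atom_type = c("OW", "HW", "HW"),
    x = c(0, r_oh * cos(half), r_oh * cos(half)),
    y = c(0, r_oh * sin(half), -r_oh * sin(half)),
    z = 0),
    bonds = matrix(c(1L, 2L, 1L, 3L), ncol = 2, byrow = TRUE))
}

.mol_ion <- function(name, element, q) {
  molecule(name, data.frame(element = element, atom_type = element,
                            x = 0, y = 0, z = 0), formal_charge = q)
}

.mol_formate <- function() {
  # sp2 carbon: H at 180 degrees, carboxylate oxygens at +/-60
  molecule("formate", data.frame(
    element = c("C", "H", "O", "O"),
    atom_type = c("C", "HC", "O", "O"),
    x = c(0, -1.10, 1.25 * cos(pi / 3), 1.25 * cos(pi / 3)),
    y = c(0, 0, 1.25 * sin(pi / 3), -1.25 * sin(pi / 3)),
    z = 0),
    bonds = matrix(c(1L, 2L, 1L, 3L, 1L, 4L), ncol = 2, byrow = TRUE),
    formal_charge = -1L)
}

.mol_ammonium <- function() {
  d <- 1.02 / sqrt(3)
  molecule("ammonium", data.frame(
    element = c("N", "H", "H", "H", "H"),
    atom_type = c("N", "HN", "HN", "HN", "HN"),
    x = c(0, d, d, -d, -d), y = c(0, d, -d, d, -d), z = c(0, d, -d, -d, d)),
    bonds = cbind(1L, 2:5),
    formal_charge = +1L)
}

#' Rigid distance scan of a dimer
#'
#' Starting from a reference side-by-side pose, the second molecule is
#' translated along the unit vector joining the closest atom pair so that the
#' separation of that pair equals each requested distance. Orientations are
#' frozen; the closest-pair identity is fixed by the reference pose.
#'
#' @param mol_a,mol_b `molecule` objects
#' @param distances positive ascending closest-pair separations (Angstrom)
#' @param dimer_id identifier stem for the frames
#' @return list of frame records (`mol_a`, `mol_b`, `xyz_a`, `xyz_b`,
#'   `frame_id`, `dimer_id`, `r_min`, `split` placeholder)
#' @export
dimer_scan <- function(mol_a, mol_b, distances,
                       dimer_id = paste(mol_a$name, mol_b$name, sep = ":")) {
  stopifnot(all(distances > 0), !is.unsorted(distances))
  xa <- coords(mol_a)
  xb0 <- coords(mol_b)
  # reference pose: b shifted along +x so the slabs are disjoint
  shift <- max(xa[, 1]) - min(xb0[, 1]) + 4
  xb0[, 1] <- xb0[, 1] + shift
  d <- .cross_dist(xa, xb0)
  ij <- which(d == min(d), arr.ind = TRUE)[1, ]
  u <- xb0[ij[2], ] - xa[ij[1], ]
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("coincident molecules in reference pose")
  u <- u / nu
  lapply(seq_along(distances), function(k) {
    xb <- sweep(xb0, 2, (distances[k] - nu) * u, `+`)
    list(mol_a = mol_a$name, mol_b = mol_b$name, xyz_a = xa, xyz_b = xb,
         frame_id = sprintf("%s|scan|%03d", dimer_id, k),
         dimer_id = dimer_id,
         r_min = min(.cross_dist(xa, xb)), split = NA_character_)
  })
}

#' Randomly oriented dimers at van der Waals contact
#'
#' Each frame applies a uniform random rotation (quaternion sampling) to the
#' second molecule and slides it along a random approach direction until the
#' first atom pair reaches `u * (R_i + R_j)`, with the contact scale `u` drawn
#' uniformly from `contact`. Deterministic per seed.
#'
#' @param mol_a,mol_b `molecule` objects
#' @param n number of frames
#' @param seed integer seed
#' @param contact range of the vdW contact scale
#' @param dimer_id identifier stem
#' @return list of frame records as in [dimer_scan()]
#' @export
random_orientations <- function(mol_a, mol_b, n, seed = 1L,
                                contact = c(0.9, 1.2),
                                dimer_id = paste(mol_a$name, mol_b$name, sep = ":")) {
  stopifnot(n > 0)
  rng <- .local_rng(seed * 7919L + 13L)
  xa <- coords(mol_a)
  acen <- colMeans(xa)
  xb_rel0 <- sweep(coords(mol_b), 2, colMeans(coords(mol_b)))
  ra <- mol_a$atoms$vdw_radius
  rb <- mol_b$atoms$vdw_radius
  frames <- vector("list", n)
  for (k in seq_len(n)) {
    # uniform rotation from a normalised 4-normal quaternion
    repeat {
      q4 <- stats::qnorm(pmin(pmax(rng(4), 1e-12), 1 - 1e-12))
      if (sum(q4^2) > 1e-12) break
    }
    q4 <- q4 / sqrt(sum(q4^2))
    Rm <- .quat_rot(q4)
    xb_rel <- xb_rel0 %*% t(Rm)
    u_scale <- contact[1] + (contact[2] - contact[1]) * rng(1)
    targets <- u_scale * outer(ra, rb, `+`)
    # approach direction: redraw until the sliding line actually reaches
    # contact (always does for directions through the molecular envelope)
    tbest <- -Inf
    tries <- 0L
    while (!is.finite(tbest)) {
      tries <- tries + 1L
      if (tries > 100L) stop("could not place contact dimer for frame ", k)
      repeat {
        v <- stats::qnorm(pmin(pmax(rng(3), 1e-12), 1 - 1e-12))
        nv <- sqrt(sum(v^2))
        if (nv > 1e-12) break
      }
      v <- v / nv
      for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb_rel))) {
        w <- xa[i, ] - acen - xb_rel[j, ]
        wv <- sum(w * v)
        disc <- wv^2 - sum(w^2) + targets[i, j]^2
        if (disc >= 0) tbest <- max(tbest, wv + sqrt(disc))
      }
    }
    xb <- sweep(xb_rel, 2, acen + tbest * v, `+`)
    frames[[k]] <- list(
      mol_a = mol_a$name, mol_b = mol_b$name, xyz_a = xa, xyz_b = xb,
      frame_id = sprintf("%s|rand|%03d", dimer_id, k),
      dimer_id = dimer_id,
      r_min = min(.cross_dist(xa, xb)), split = NA_character_)
  }
  frames[!vapply(frames, is.null, logical(1))]
}

.quat_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# stable string hash for split assignment (survives regeneration)
.stable_hash <- function(s) {
  vapply(s, function(si) {
    h <- 0
    for (b in utf8ToInt(si)) h <- (h * 31 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Reference energy components for a set of dimer frames
#'
#' Evaluates the ground-truth model on every frame: electrostatics from the
#' distributed-charge Coulomb sum; induction from shell relaxation when the
#' ground truth is polarizable, otherwise a documented proxy
#' `-frac |Elec| exp(-damp r_min)`; and an exchange proxy
#' `A_x exp(-b_x r_min)` that exists only to exercise the selection filters.
#' Optional Gaussian noise is added to the electrostatic and induction
#' components. Frames are assigned to train/test by a stable hash of the
#' frame id at 2:1 (a frame is `test` when `hash %% 3 == 0`), so the split
#' survives regeneration.
#'
#' @param gt a `ground_truth`
#' @param frames list of frame records from [dimer_scan()] /
#'   [random_orientations()]
#' @param noise_sigma additive Gaussian noise s.d. (kJ/mol), default 0
#' @param seed seed for the noise stream
#' @param induc_frac,induc_damp induction-proxy parameters for nonpolarizable
#'   ground truths
#' @param A_x,b_x exchange-proxy amplitude (kJ/mol) and range (1/Angstrom)
#' @return a `ref_dataset`: `molecules`, `frames` (with splits assigned),
#'   `components` data frame, `meta`
#' @export
reference_components <- function(gt, frames, noise_sigma = 0, seed = 1L,
                                 induc_frac = 0.15, induc_damp = 0.6,
                                 A_x = 2.4e5, b_x = 3.0) {
  stopifnot(inherits(gt, "ground_truth"))
  ids <- vapply(frames, `[[`, "", "frame_id")
  split <- ifelse(.stable_hash(ids) %% 3 == 0, "test", "train")
  for (k in seq_along(frames)) frames[[k]]$split <- split[k]
  skeleton <- list(molecules = gt$molecules, frames = frames)
  polar <- gt$model$shell
  pred <- predict_components(gt$ff, gt$model, skeleton, need_induc = polar)
  r_min <- vapply(frames, `[[`, 0, "r_min")
  elec <- pred$elec
  induc <- if (polar) pred$induc else -induc_frac * abs(elec) * exp(-induc_damp * r_min)
  if (noise_sigma > 0) {
    rng <- .local_rng(seed * 104729L + 7L)
    gauss <- function(n) stats::qnorm(pmin(pmax(rng(n), 1e-12), 1 - 1e-12))
    elec <- elec + noise_sigma * gauss(length(elec))
    induc <- induc + noise_sigma * gauss(length(induc))
  }
  comp <- data.frame(
    dimer_id = vapply(frames, `[[`, "", "dimer_id"),
    frame_id = ids, r_min_A = r_min,
    E_elec_kJmol = elec, E_induc_kJmol = induc,
    E_exch_proxy_kJmol = A_x * exp(-b_x * r_min),
    split = split)
  structure(list(molecules = gt$molecules, frames = frames,
                 components = comp,
                 meta = list(seed = seed, noise_sigma = noise_sigma,
                             polarizable = polar,
                             induction_proxy = !polar,
                             generator = "elecff-synthetic-1")),
            class = "ref_dataset")
}

#' @export
print.ref_dataset <- function(x, ...) {
  cat(sprintf("<ref_dataset> %d frames (%d train / %d test), %d molecules%s\n",
              length(x$frames), sum(x$components$split == "train"),
              sum(x$components$split == "test"), length(x$molecules),
              if (isTRUE(x$meta$induction_proxy)) "; induction is a proxy" else ""))
  invisible(x)
}

#' Apply the distance and exchange-energy selection filters
#'
#' Keeps frames with `r_min < d_max` and exchange proxy `< exch_max`, both
#' strict inequalities. Defaults mirror the standard selection: 6 Angstrom
#' and 0.04 hartree (= 105.0 kJ/mol).
#'
#' @param data a `ref_dataset`
#' @param d_max distance cutoff (Angstrom)
#' @param exch_max exchange cutoff (kJ/mol)
#' @return the filtered `ref_dataset`; counts are recorded in `meta$filter`
#' @export
apply_filters <- function(data, d_max = 6, exch_max = 0.04 * HARTREE_TO_KJMOL) {
  stopifnot(inherits(data, "ref_dataset"))
  keep <- data$components$r_min_A < d_max &
    data$components$E_exch_proxy_kJmol < exch_max
  out <- data
  out$frames <- data$frames[keep]
  out$components <- data$components[keep, , drop = FALSE]
  rownames(out$components) <- NULL
  out$meta$filter <- list(d_max = d_max, exch_max = exch_max,
                          n_in = length(keep), n_kept = sum(keep))
  out
}
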