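# Shared fixtures, all built in code.

# idealized acetate CH3COO- (7 atoms): methyl carbon, carboxyl carbon,
# three methyl hydrogens, two carboxylate oxygens
make_acetate <- function() {
  d <- 1.09 / sqrt(3)
  molecule("acetate", data.frame(
    element = c("C", "C", "H", "H", "H", "O", "O"),
    atom_type = c("CT", "C", "HC", "HC", "HC", "O", "O"),
    x = c(0, 1.52, -d, -d, d, 1.52 + 1.25 * cos(pi / 3), 1.52 + 1.25 * cos(pi / 3)),
    y = c(0, 0, d, -d, d, 1.25 * sin(pi / 3), -1.25 * sin(pi / 3)),
    z = c(0, 0, d, d, -d, 0, 0)),
    bonds = matrix(c(1L, 2L, 1L, 3L, 1L, 4L, 1L, 5L, 2L, 6L, 2L, 7L),
                   ncol = 2, byrow = TRUE),
    formal_charge = -1L)
}

acetate_ff <- function() {
  force_field(
    data.frame(type = c("CT", "C", "HC", "O"),
               chi = c(5.0, 5.5, 2.2, 8.8), eta = c(10, 10, 15, 11),
               q_V = c(-0.9, -0.9, -0.4, -1.4),
               zeta_V = c(1.8, 1.8, 2.3, 1.6),
               zeta = c(2.0, 2.0, 2.5, 1.8), alpha = c(0.8, 0.8, 0.3, 0.8)),
    data.frame(type1 = c("C", "CT", "C"), type2 = c("CT", "HC", "O"),
               delta_chi = c(0.2, 2.8, -0.6), delta_eta = c(8, 9, 7)))
}

# TIP4P-ish water force field with both SQE and carrier parameters
water_ff <- function(r_OM = 0.125) {
  force_field(
    data.frame(type = c("OW", "HW"), chi = c(8.5, 4.0), eta = c(11, 14),
               q_V = c(-1.3, -0.45), zeta_V = c(1.7, 2.2),
               zeta = c(1.9, 2.4), alpha = c(0.8, 0.25)),
    data.frame(type1 = "HW", type2 = "OW", delta_chi = -0.5, delta_eta = 8),
    r_OM = r_OM)
}

water_molecule <- function() elecff:::.mol_water()

# random tree-shaped molecule + matching force field for SQE property tests
random_molecule_ff <- function(rng) {
  n <- 2L + floor(rng(1) * 7)          # 2..8 atoms
  ntypes <- 1L + floor(rng(1) * 3)
  types <- paste0("T", 1:ntypes)
  atype <- types[1L + floor(rng(n) * ntypes)]
  # random tree: connect atom i (i>1) to a random earlier atom
  bonds <- cbind(1L + floor(rng(n - 1) * (seq_len(n - 1))), 2:n)
  q <- c(-1L, 0L, 0L, 1L)[1L + floor(rng(1) * 4)]
  mol <- molecule("rnd", data.frame(
    element = "C", atom_type = atype,
    x = rng(n) * 10, y = rng(n) * 10, z = rng(n) * 10),
    bonds = bonds, formal_charge = q)
  pairs <- unique(t(apply(bonds, 1, function(b) sort(atype[b]))))
  dchi <- 4 * rng(nrow(pairs)) - 2
  dchi[pairs[, 1] == pairs[, 2]] <- 0   # homonuclear bonds carry no bias
  ff <- force_field(
    data.frame(type = types, chi = 1 + 10 * rng(ntypes),
               eta = 2 + 20 * rng(ntypes)),
    data.frame(type1 = pairs[, 1], type2 = pairs[, 2],
               delta_chi = dchi,
               delta_eta = 1 + 10 * rng(nrow(pairs))))
  list(mol = mol, ff = ff)
}

# rigid rotation + translation applied to a coordinate matrix
rigid_motion <- function(xyz, seed) {
  rng <- elecff:::.local_rng(seed)
  q4 <- stats::qnorm(rng(4)); q4 <- q4 / sqrt(sum(q4^2))
  R <- elecff:::.quat_rot(q4)
  t <- 10 * (rng(3) - 0.5)
  sweep(xyz %*% t(R), 2, t, `+`)
}
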