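#' Default trainable-parameter bounds
#'
#' Bounds by parameter field, applied when a trainable spec is built without
#' explicit bounds: chi 0-20 V, eta 1-50 V/e, delta_chi -10-10 V, delta_eta
#' 0.1-50 V/e, distribution widths 0.3-10 1/A, q_V -4-0 e, alpha 0-5 A^3,
#' A_ic 0-500 kJ/mol, b_ic 0.5-6 1/A, r_OM 0-0.3 A.
#'
#' @param paths character vector of parameter paths (see [ff_get()])
#' @return two-column matrix of lower/upper bounds
#' @export
default_bounds <- function(paths) {
  tbl <- list(chi = c(0, 20), eta = c(1, 50), delta_chi = c(-10, 10),
              delta_eta = c(0.1, 50), zeta = c(0.3, 10), zeta_V = c(0.3, 10),
              q_V = c(-4, 0), alpha = c(0, 5), A_ic = c(0, 500),
              b_ic = c(0.5, 6), r_OM = c(0, 0.3))
  out <- t(vapply(paths, function(p) {
    field <- utils::tail(strsplit(p, ".", fixed = TRUE)[[1]], 1)
    if (is.null(tbl[[field]])) stop("no default bounds for parameter '", p, "'")
    tbl[[field]]
  }, numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}

#' Specify which force-field parameters are trained, and against what
#'
#' @param paths parameter paths (see [ff_get()])
#' @param lower,upper bounds; defaults from [default_bounds()]
#' @param target training target: `"ESP"` (grid residual with per-evaluation
#'   charge refitting), `"Elec"` (electrostatic component), `"Elec+Induc"`
#'   (residual of the summed components) or `"Elec,Induc"` (simultaneous
#'   fitting of both components without summing)
#' @param weights component weights for the simultaneous target
#'   (`c(elec, induc)`)
#' @return a `trainable_spec`
#' @export
trainable_spec <- function(paths, lower = NULL, upper = NULL,
                           target = c("Elec", "Elec+Induc", "Elec,Induc", "ESP"),
                           weights = c(1, 1)) {
  target <- match.arg(target)
  if (is.null(lower) || is.null(upper)) {
    b <- default_bounds(paths)
    if (is.null(lower)) lower <- b[, 1]
    if (is.null(upper)) upper <- b[, 2]
  }
  stopifnot(length(lower) == length(paths), length(upper) == length(paths),
            all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))
  structure(list(paths = paths, lower = as.numeric(lower),
                 upper = as.numeric(upper), target = target,
                 weights = weights),
            class = "trainable_spec")
}

#' Configuration of the hybrid GA/MC optimizer
#'
#' Defaults follow the standard recipe: 20 generations, 40 Monte-Carlo
#' refinement iterations per generation at a fitness "temperature" of 0.01,
#' and a penalty force constant of 20000 per e^2 against unchemical charges.
#' Population 256 suits nonpolarizable models; 512 is used for polarizable
#' ones.
#'
#' @param pop_size population size (>= 2)
#' @param generations GA generations
#' @param mc_iterations Metropolis steps per individual per generation
#' @param temperature Metropolis temperature in fitness units
#' @param penalty_k penalty force constant (per e^2)
#' @param cx_prob crossover probability
#' @param mut_prob per-gene mutation probability
#' @param mut_scale mutation s.d. as a fraction of the bound width
#' @param mc_scale MC proposal s.d. as a fraction of the bound width
#' @param seed RNG seed (recorded in outputs)
#' @return a `ga_mc_config`
#' @export
ga_mc_config <- function(pop_size = 256, generations = 20, mc_iterations = 40,
                         temperature = 0.01, penalty_k = 20000,
                         cx_prob = 0.9, mut_prob = 0.15, mut_scale = 0.1,
                         mc_scale = 0.01, seed = 1L) {
  stopifnot(pop_size >= 2, generations >= 1, mc_iterations >= 0,
            temperature > 0, penalty_k >= 0, cx_prob > 0, cx_prob <= 1,
            mut_prob >= 0, mut_prob <= 1, mut_scale > 0, mc_scale > 0)
  structure(as.list(environment()), class = "ga_mc_config")
}

## ---------------------------------------------------------------------------
## Compiled dataset evaluator
## ---------------------------------------------------------------------------

# parse parameter paths once into direct (section, row, column) slots
.parse_paths <- function(ff, paths) {
  lapply(paths, function(p) {
    q <- strsplit(p, ".", fixed = TRUE)[[1]]
    if (q[1] == "atom") {
      i <- match(q[2], ff$atom_types$type)
      if (is.na(i) || is.null(ff$atom_types[[q[3]]]))
        stop("cannot resolve parameter path '", p, "'")
      list(sec = "atom", i = i, col = q[3])
    } else if (q[1] == "bond") {
      tt <- sort(strsplit(q[2], "-", fixed = TRUE)[[1]])
      i <- which(ff$bond_types$type1 == tt[1] & ff$bond_types$type2 == tt[2])
      if (!length(i) || is.null(ff$bond_types[[q[3]]]))
        stop("cannot resolve parameter path '", p, "'")
      list(sec = "bond", i = i, col = q[3])
    } else if (q[1] == "global") {
      if (is.null(ff$global[[q[2]]]))
        stop("cannot resolve parameter path '", p, "'")
      list(sec = "global", col = q[2])
    } else stop("cannot resolve parameter path '", p, "'")
  })
}

.apply_params <- function(ff, slots, par) {
  for (k in seq_along(slots)) {
    s <- slots[[k]]
    if (s$sec == "atom") ff$atom_types[[s$col]][s$i] <- par[k]
    else if (s$sec == "bond") ff$bond_types[[s$col]][s$i] <- par[k]
    else ff$global[[s$col]] <- par[k]
  }
  ff
}

# precompute per-molecule SQE structure (incidence, index maps)
.sqe_compile <- function(mol, ff) {
  n <- nrow(mol$atoms); m <- nrow(mol$bonds)
  types <- mol$atoms$atom_type
  aidx <- match(types, ff$atom_types$type)
  if (anyNA(aidx)) stop("atom type missing from force field")
  Tm <- matrix(0, n, m)
  bidx <- integer(m)
  for (k in seq_len(m)) {
    i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
    ti <- types[i]; tj <- types[j]
    if (tj < ti || (tj == ti && j < i)) { tmp <- i; i <- j; j <- tmp; tmp <- ti; ti <- tj; tj <- tmp }
    Tm[i, k] <- 1; Tm[j, k] <- -1
    t1 <- min(ti, tj); t2 <- max(ti, tj)
    w <- which(ff$bond_types$type1 == t1 & ff$bond_types$type2 == t2)
    if (!length(w)) stop("bond type '", t1, "-", t2, "' not in force field")
    bidx[k] <- w
  }
  list(T = Tm, aidx = aidx, bidx = bidx,
       q_ref = rep(mol$formal_charge / n, n),
       is_h = mol$atoms$element == "H")
}

.sqe_solve_fast <- function(cmp, ff) {
  m <- length(cmp$bidx)
  if (m == 0L) return(cmp$q_ref)
  eta <- ff$atom_types$eta[cmp$aidx]
  chi <- ff$atom_types$chi[cmp$aidx]
  dchi <- ff$bond_types$delta_chi[cmp$bidx]
  deta <- ff$bond_types$delta_eta[cmp$bidx]
  A <- crossprod(cmp$T, cmp$T * eta) + diag(deta, m)
  b <- as.vector(crossprod(cmp$T, chi + eta * cmp$q_ref)) + dchi
  p <- solve(A, -b)
  as.vector(cmp$q_ref + cmp$T %*% p)
}

# site template of one molecule instance at a given geometry
.site_template <- function(mol, model, ff, xyz) {
  n <- nrow(mol$atoms)
  expanded <- !is.null(model$vsite_kind) || model$shell
  ck <- if (model$shell) model$shell_kind else model$vsite_kind
  if (expanded) {
    parent <- rep(seq_len(n), each = 2)
    role <- rep(c("core", "carrier"), n)
    kind <- rep(c(model$core_kind, ck), n)
  } else {
    parent <- seq_len(n)
    role <- rep("core", n)
    kind <- rep(model$core_kind, n)
  }
  pos <- xyz[parent, , drop = FALSE]
  if (model$water_sites == "4P" && .water_like(mol)) {
    m <- water_msite(set_coords(mol, xyz), ff$global$r_OM)
    io <- which(mol$atoms$element == "O")
    pos[parent == io, ] <- matrix(m, sum(parent == io), 3, byrow = TRUE)
  }
  list(pos = pos, parent = parent, role = role, kind = kind,
       types = mol$atoms$atom_type[parent], expanded = expanded,
       shell = model$shell)
}

# compile a dataset (frames restricted to `split` if given) for fast
# repeated evaluation under changing parameters; geometry is frozen, so
# r_OM must not be trainable when 4P water is present
.compile_dataset <- function(ff, model, data, split = NULL) {
  frames <- data$frames
  comp <- data$components
  if (!is.null(split)) {
    keep <- comp$split %in% split
    frames <- frames[keep]
    comp <- comp[keep, , drop = FALSE]
  }
  used <- unique(unlist(lapply(frames, function(f) c(f$mol_a, f$mol_b))))
  mols <- data$molecules[used]
  sqe <- lapply(mols, .sqe_compile, ff = ff)
  offs <- c(0, cumsum(vapply(mols, function(m) nrow(m$atoms), 0)))
  names(offs) <- c(names(mols), "..end")
  tidx_all <- match(unlist(lapply(mols, function(m) m$atoms$atom_type)),
                    ff$atom_types$type)
  polar <- model$shell

  fr_data <- lapply(frames, function(fr) {
    ta <- .site_template(mols[[fr$mol_a]], model, ff, fr$xyz_a)
    tb <- .site_template(mols[[fr$mol_b]], model, ff, fr$xyz_b)
    na <- nrow(ta$pos); nb <- nrow(tb$pos)
    ia <- rep(seq_len(na), nb); ib <- rep(seq_len(nb), each = na)
    r <- as.vector(.cross_dist(ta$pos, tb$pos))
    list(ta = ta, tb = tb, ia = ia, ib = ib, r = r,
         cid_a = offs[[fr$mol_a]] + ta$parent,
         cid_b = offs[[fr$mol_b]] + tb$parent,
         mol_a = fr$mol_a, mol_b = fr$mol_b)
  })

  # flattened nonpolarizable fast path
  nfr <- length(fr_data)
  fid <- unlist(lapply(seq_len(nfr), function(k) rep(k, length(fr_data[[k]]$r))))
  flat <- list(
    fid = fid,
    r = unlist(lapply(fr_data, `[[`, "r")),
    kind_a = unlist(lapply(fr_data, function(f) f$ta$kind[f$ia])),
    kind_b = unlist(lapply(fr_data, function(f) f$tb$kind[f$ib])),
    role_a = unlist(lapply(fr_data, function(f) f$ta$role[f$ia])),
    role_b = unlist(lapply(fr_data, function(f) f$tb$role[f$ib])),
    ti_a = unlist(lapply(fr_data, function(f) match(f$ta$types[f$ia], ff$atom_types$type))),
    ti_b = unlist(lapply(fr_data, function(f) match(f$tb$types[f$ib], ff$atom_types$type))),
    cid_a = unlist(lapply(fr_data, function(f) f$cid_a[f$ia])),
    cid_b = unlist(lapply(fr_data, function(f) f$cid_b[f$ib])))

  expanded <- fr_data[[1]]$ta$expanded
  list(frames = fr_data, flat = flat, comp = comp, sqe = sqe, mols = mols,
       offs = offs, tidx_all = tidx_all, model = model, polar = polar,
       expanded = expanded, n_frames = nfr,
       is_h = unlist(lapply(mols, function(m) m$atoms$element == "H")))
}

# atomic charges (concatenated over the molecule library) under ff
.charges_all <- function(ctx, ff) {
  unlist(lapply(ctx$sqe, .sqe_solve_fast, ff = ff), use.names = FALSE)
}

# site-level q and zeta from atom charges + per-type parameters
.site_q_zeta <- function(ctx, ff, qatom) {
  at <- ff$atom_types
  fl <- ctx$flat
  qV_a <- at$q_V[fl$ti_a]; qV_b <- at$q_V[fl$ti_b]
  core_a <- fl$role_a == "core"; core_b <- fl$role_b == "core"
  qa <- ifelse(core_a, qatom[fl$cid_a] - if (ctx$expanded) qV_a else 0, qV_a)
  qb <- ifelse(core_b, qatom[fl$cid_b] - if (ctx$expanded) qV_b else 0, qV_b)
  za <- ifelse(core_a, at$zeta[fl$ti_a], at$zeta_V[fl$ti_a])
  zb <- ifelse(core_b, at$zeta[fl$ti_b], at$zeta_V[fl$ti_b])
  za[core_a & fl$kind_a == "point"] <- NA_real_
  zb[core_b & fl$kind_b == "point"] <- NA_real_
  list(qa = qa, qb = qb, za = za, zb = zb)
}

# fast per-frame electrostatic energies (shells at rest)
.elec_fast <- function(ctx, ff, qatom) {
  sq <- .site_q_zeta(ctx, ff, qatom)
  fl <- ctx$flat
  f <- .shape_vec(fl$kind_a, sq$za, fl$kind_b, sq$zb, fl$r)
  as.vector(rowsum(KE_COULOMB * sq$qa * sq$qb * f, fl$fid,
                   reorder = TRUE))
}

# per-frame induction energies by shell relaxation (polarizable models)
.induc_fast <- function(ctx, ff, qatom) {
  at <- ff$atom_types
  out <- numeric(ctx$n_frames)
  for (k in seq_len(ctx$n_frames)) {
    f <- ctx$frames[[k]]
    prep <- function(t, cid0) {
      ti <- match(t$types, at$type)
      core <- t$role == "core"
      q <- ifelse(core, 0, at$q_V[ti])   # atom charges filled below
      q[core] <- qatom[cid0[core]] - at$q_V[ti[core]]
      z <- ifelse(core, at$zeta[ti], at$zeta_V[ti])
      z[core & t$kind == "point"] <- NA_real_
      springs <- rep(NA_real_, length(q))
      sh <- which(t$role == "carrier" & t$shell)
      springs[sh] <- KE_COULOMB * at$q_V[ti[sh]]^2 / at$alpha[ti[sh]]
      list(q = q, z = z, springs = springs, sh = sh)
    }
    pa <- prep(f$ta, f$cid_a)
    pb <- prep(f$tb, f$cid_b)
    core <- .relax_core(
      xa0 = f$ta$pos, xb0 = f$tb$pos,
      kin_a = f$ta$kind, za = pa$z, qa = pa$q,
      kin_b = f$tb$kind, zb = pb$z, qb = pb$q,
      sha = pa$sh, shb = pb$sh,
      springs = c(pa$springs[pa$sh], pb$springs[pb$sh]),
      gtol = 1e-5)
    e_ind <- core$e_min - core$e_rest
    if (isTRUE(ctx$model$induction_correction)) {
      d <- f$r[f$ta$role[f$ia] == "core" & f$tb$role[f$ib] == "core"]
      e_ind <- e_ind - ff$global$A_ic * sum(exp(-ff$global$b_ic * d))
    }
    out[k] <- e_ind
  }
  out
}

#' Fitness of a parameter vector against a reference dataset
#'
#' The score is the component mean-squared deviation (weighted, for the
#' simultaneous target) plus the chemical-sanity penalty
#' `penalty_k * sum(q_H^2)` over hydrogen atoms with negative SQE charges.
#' For the `"ESP"` target the point/core charges are refitted to each grid
#' inside the evaluation and the grid residual MSD is scored.
#'
#' @param par parameter vector matching `spec$paths`
#' @param ff0 base `force_field`
#' @param model a `model_definition`
#' @param data a `ref_dataset` (energy targets) or list of
#'   `list(mol, grid, Q)` items (ESP target)
#' @param spec a `trainable_spec`
#' @param penalty_k penalty force constant per e^2
#' @param split which split to score (default `"train"`)
#' @return the scalar fitness (lower is better), with attributes `msd` and
#'   `penalty`
#' @export
ff_fitness <- function(par, ff0, model, data, spec, penalty_k = 20000,
                       split = "train") {
  if (spec$target == "ESP") {
    f <- .make_fitness_esp(ff0, model, data, spec, penalty_k)
  } else {
    ctx <- .compile_dataset(ff0, model, data, split = split)
    f <- .make_fitness_energy(ff0, model, ctx, spec, penalty_k)
  }
  f(par)
}

.make_fitness_energy <- function(ff0, model, ctx, spec, penalty_k) {
  slots <- .parse_paths(ff0, spec$paths)
  target <- spec$target
  w <- spec$weights
  ref_e <- ctx$comp$E_elec_kJmol
  ref_i <- ctx$comp$E_induc_kJmol
  need_induc <- target %in% c("Elec+Induc", "Elec,Induc")
  function(par) {
    ff <- .apply_params(ff0, slots, par)
    out <- tryCatch({
      qatom <- .charges_all(ctx, ff)
      pen <- penalty_k * sum(pmin(qatom[ctx$is_h], 0)^2)
      elec <- .elec_fast(ctx, ff, qatom)
      induc <- if (need_induc && ctx$polar) .induc_fast(ctx, ff, qatom)
        else if (need_induc && isTRUE(model$induction_correction)) {
          # nonpolarizable but with the Born-Mayer correction as "induction"
          vapply(seq_len(ctx$n_frames), function(k) {
            f <- ctx$frames[[k]]
            d <- f$r[f$ta$role[f$ia] == "core" & f$tb$role[f$ib] == "core"]
            -ff$global$A_ic * sum(exp(-ff$global$b_ic * d))
          }, numeric(1))
        } else numeric(ctx$n_frames)
      msd <- switch(target,
        "Elec" = mean((elec - ref_e)^2),
        "Elec+Induc" = mean((elec + induc - (ref_e + ref_i))^2),
        "Elec,Induc" = w[1] * mean((elec - ref_e)^2) +
                       w[2] * mean((induc - ref_i)^2))
      structure(msd + pen, msd = msd, penalty = pen)
    }, error = function(e) structure(1e10, msd = 1e10, penalty = 0))
    out
  }
}

.make_fitness_esp <- function(ff0, model, data, spec, penalty_k) {
  slots <- .parse_paths(ff0, spec$paths)
  function(par) {
    ff <- .apply_params(ff0, slots, par)
    out <- tryCatch({
      msds <- pens <- numeric(length(data))
      for (k in seq_along(data)) {
        it <- data[[k]]
        fit <- fit_charges_to_esp(it$mol, model, ff, it$grid,
                                  Q_total = it$mol$formal_charge)
        msds[k] <- fit$rmsd^2
        hq <- fit$charges[it$mol$atoms$element == "H"]
        pens[k] <- penalty_k * sum(pmin(hq, 0)^2)
      }
      structure(mean(msds) + sum(pens), msd = mean(msds), penalty = sum(pens))
    }, error = function(e) structure(1e10, msd = 1e10, penalty = 0))
    out
  }
}

#' Train force-field parameters with the hybrid GA/MC optimizer
#'
#' Genetic algorithm (tournament selection of size 2, uniform crossover,
#' Gaussian mutation scaled to the bound width, elitism) with a Metropolis
#' Monte-Carlo refinement of every individual in each generation. The best
#' individual is tracked across generations, so the best-so-far train fitness
#' is non-increasing. Identical seeds and inputs give bit-identical
#' histories.
#'
#' @param ff0 starting `force_field`
#' @param model the `model_definition` being trained
#' @param data a `ref_dataset` (or ESP item list for the `"ESP"` target)
#' @param spec a `trainable_spec`
#' @param cfg a [ga_mc_config()]
#' @return list with `ff` (best parameters applied), `par`, `history` data
#'   frame (generation, best, mean, penalty_share), `best_fitness`, `spec`,
#'   `cfg`, and a train/test `eval_report` for energy targets
#' @export
train_ff <- function(ff0, model, data, spec, cfg = ga_mc_config()) {
  stopifnot(inherits(spec, "trainable_spec"), inherits(cfg, "ga_mc_config"),
            inherits(model, "model_definition"))
  d <- length(spec$paths)
  if (d == 0L) {
    fit <- ff_fitness(numeric(0), ff0, model, data, spec, cfg$penalty_k)
    return(list(ff = ff0, par = numeric(0), history = NULL,
                best_fitness = as.numeric(fit), spec = spec, cfg = cfg))
  }
  if (cfg$pop_size < 2) stop("population must hold at least 2 individuals")
  if (spec$target == "ESP") {
    fit_fn <- .make_fitness_esp(ff0, model, data, spec, cfg$penalty_k)
  } else {
    ctx <- .compile_dataset(ff0, model, data, split = "train")
    if ("global.r_OM" %in% spec$paths && model$water_sites == "4P" &&
        any(vapply(data$molecules, .water_like, logical(1))))
      stop("r_OM cannot be trained on a geometry-compiled dataset; fix r_OM or use 3P water")
    fit_fn <- .make_fitness_energy(ff0, model, ctx, spec, cfg$penalty_k)
  }

  lo <- spec$lower; hi <- spec$upper; width <- hi - lo
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)

  pop <- matrix(stats::runif(cfg$pop_size * d), cfg$pop_size, d)
  pop <- sweep(sweep(pop, 2, width, `*`), 2, lo, `+`)
  scores <- apply(pop, 1, function(p) as.numeric(fit_fn(p)))
  if (!any(is.finite(scores)) || all(scores >= 1e10))
    stop("all individuals of the initial population are infeasible")

  best_i <- which.min(scores)
  best_par <- pop[best_i, ]; best_score <- scores[best_i]
  hist <- vector("list", cfg$generations)

  clamp <- function(x) pmin(pmax(x, lo), hi)
  for (gen in seq_len(cfg$generations)) {
    # --- GA step: elitism + tournament/crossover/mutation offspring
    newpop <- matrix(0, cfg$pop_size, d)
    newpop[1, ] <- best_par
    for (i in 2:cfg$pop_size) {
      c1 <- sample.int(cfg$pop_size, 2)
      p1 <- c1[which.min(scores[c1])]
      c2 <- sample.int(cfg$pop_size, 2)
      p2 <- c2[which.min(scores[c2])]
      child <- pop[p1, ]
      if (stats::runif(1) < cfg$cx_prob) {
        mask <- stats::runif(d) < 0.5
        child[mask] <- pop[p2, mask]
      }
      mut <- stats::runif(d) < cfg$mut_prob
      if (any(mut))
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, cfg$mut_scale * width[mut])
      newpop[i, ] <- clamp(child)
    }
    pop <- newpop
    scores <- apply(pop, 1, function(p) as.numeric(fit_fn(p)))

    # --- MC refinement of every individual
    if (cfg$mc_iterations > 0) {
      for (i in seq_len(cfg$pop_size)) {
        cur <- pop[i, ]; cs <- scores[i]
        for (it in seq_len(cfg$mc_iterations)) {
          prop <- clamp(cur + stats::rnorm(d, 0, cfg$mc_scale * width))
          ps <- as.numeric(fit_fn(prop))
          if (ps <= cs || stats::runif(1) < exp(-(ps - cs) / cfg$temperature)) {
            cur <- prop; cs <- ps
          }
        }
        pop[i, ] <- cur; scores[i] <- cs
      }
    }
    gi <- which.min(scores)
    if (scores[gi] < best_score) {
      best_score <- scores[gi]; best_par <- pop[gi, ]
    }
    fb <- fit_fn(best_par)
    hist[[gen]] <- data.frame(
      generation = gen, best = best_score, mean = mean(scores),
      penalty_share = if (best_score > 0) attr(fb, "penalty") / best_score else 0)
  }

  ff_best <- .apply_params(ff0, .parse_paths(ff0, spec$paths), best_par)
  out <- list(ff = ff_best, par = best_par, history = do.call(rbind, hist),
              best_fitness = best_score, spec = spec, cfg = cfg)
  if (spec$target != "ESP" && inherits(data, "ref_dataset")) {
    comps <- if (spec$target == "Elec") "Elec" else c("Elec", "Induc", "Elec+Induc")
    comps <- intersect(comps, c("Elec", if (model$shell || model$induction_correction) c("Induc", "Elec+Induc") else "Elec+Induc"))
    out$report <- evaluate_ff(ff_best, model, data, components = comps)
  }
  out
}
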