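# Synthetic stand-in for MD/DFT engines: united-atom chain toys with known
# harmonic bending terms and torsional cosine-series potentials, sampled from
# the exact Boltzmann distribution of the internal coordinates by Metropolis
# Monte Carlo (bond lengths and rotor attachment angles fixed by
# construction, emulating constrained bonds).  Brute-force quadrature and
# closed-form harmonic oracles provide ground truth for every estimated
# quantity.

# ---- coordinate potentials ---------------------------------------------

cosine_potential <- function(coef) {
  # V(phi) = sum_n c_n (1 + cos(n phi)); minimum 0 at phi = pi for c_n > 0
  # on odd n
  ns <- as.numeric(names(coef))
  cs <- as.numeric(coef)
  function(q) {
    v <- 0
    for (i in seq_along(ns)) v <- v + cs[i] * (1 + cos(ns[i] * q))
    v
  }
}

harmonic_potential <- function(k, q0, periodic = FALSE) {
  force(k); force(q0); force(periodic)
  if (periodic) {
    # wrapped difference: harmonic in the torsion angle, continuous at +/- pi
    function(q) {
      d <- ((q - q0 + pi) %% (2 * pi)) - pi
      0.5 * k * d^2
    }
  } else {
    function(q) 0.5 * k * (q - q0)^2
  }
}

# numeric curvature at the minimum
coord_curvature <- function(U, qmin, h = 1e-4) {
  (U(qmin + h) - 2 * U(qmin) + U(qmin - h)) / h^2
}

make_coord <- function(type, potential, params) {
  if (potential == "cosine") {
    U <- cosine_potential(params$coef)
    # locate the global minimum on a grid, then refine
    g <- seq(-pi, pi, length.out = 721)[-721]
    q0 <- g[which.min(U(g))]
    qmin <- stats::optimize(U, c(q0 - 0.02, q0 + 0.02))$minimum
  } else {
    U <- harmonic_potential(params$k, params$q0, periodic = (type == "torsion"))
    qmin <- params$q0
  }
  list(type = type, potential = potential, params = params, U = U,
       qmin = qmin, curvature = coord_curvature(U, qmin),
       periodic = (type == "torsion"))
}

# ---- model builders -----------------------------------------------------

#' United-atom chain toy model
#'
#' A chain of `n_heavy` united atoms with fixed bond lengths, harmonic
#' bending terms on every heavy-atom triple, multi-well cosine backbone
#' torsions and (for `n_heavy >= 3`) one single-well "methyl-like" rotor
#' site on each terminal atom.  The sampled internal coordinates are the
#' bends and torsions; bonds and rotor attachment angles are fixed by
#' construction (in the Cartesian potential they appear as stiff springs, so
#' the corresponding normal modes are high-frequency, i.e. quantum-like).
#'
#' @param n_heavy Number of chain atoms (>= 2).
#' @param torsion `"butane"` for the multi-well cosine backbone series or
#'   `"harmonic"` for a fully harmonic toy.
#' @param bond_cc,bond_rotor Bond lengths (nm).
#' @param k_theta,theta0 Bending force constant (kJ/mol/rad^2) and
#'   equilibrium angle (rad).
#' @param backbone_coef Named coefficients `c_n` of the backbone cosine
#'   series `sum c_n (1 + cos(n phi))` (kJ/mol).
#' @param rotor_coef Same for the rotor torsions.
#' @param k_backbone,k_rotor Harmonic torsion constants for
#'   `torsion = "harmonic"` (kJ/mol/rad^2).
#' @param m_end,m_mid,m_rotor Masses (amu).
#' @param k_bond,k_fix Stiff spring constants of the Cartesian evaluator for
#'   the constrained bonds (kJ/mol/nm^2) and fixed rotor angles
#'   (kJ/mol/rad^2).
#' @return Object of class `"qge_toy"` with fields `masses`, `zmat`,
#'   `coords` (sampled-coordinate descriptors), `topology`, `ground_truth`
#'   and `potential` (the Cartesian evaluator).
#' @export
build_chain_model <- function(n_heavy = 4,
                              torsion = c("butane", "harmonic"),
                              bond_cc = 0.153, bond_rotor = 0.15,
                              k_theta = 520, theta0 = 1.9373,
                              backbone_coef = c("1" = 2.9, "3" = 5.92),
                              rotor_coef = c("1" = 7.5),
                              k_backbone = 30, k_rotor = 15,
                              m_end = 15.035, m_mid = 14.027, m_rotor = 4.0,
                              k_bond = 2.5e5, k_fix = 450) {
  torsion <- match.arg(torsion)
  stopifnot(n_heavy >= 2)
  has_rotors <- n_heavy >= 3
  n_atoms <- n_heavy + if (has_rotors) 2L else 0L
  masses <- c(if (n_heavy == 2) c(m_end, m_end)
              else c(m_end, rep(m_mid, n_heavy - 2), m_end),
              if (has_rotors) c(m_rotor, m_rotor))

  coords <- list()
  zmat <- vector("list", n_atoms)
  theta_fix <- 1.92   # rotor attachment angle, rad

  # heavy chain
  zmat[[1]] <- NULL
  if (n_heavy >= 2) zmat[[2]] <- list(j = 1L, bond = bond_cc)
  for (i in seq_len(n_heavy)[-(1:2)]) {
    ci <- length(coords) + 1L
    coords[[ci]] <- make_coord("bend", "harmonic",
                               list(k = k_theta, q0 = theta0))
    if (i == 3L) {
      zmat[[3]] <- list(j = 2L, k = 1L, bond = bond_cc, angle = ci)
    } else {
      ti <- length(coords) + 1L
      coords[[ti]] <- if (torsion == "butane")
        make_coord("torsion", "cosine", list(coef = backbone_coef))
      else make_coord("torsion", "harmonic", list(k = k_backbone, q0 = pi))
      zmat[[i]] <- list(j = i - 1L, k = i - 2L, l = i - 3L, bond = bond_cc,
                        angle = ci, dihedral = ti)
    }
  }
  # reorder: above loop appended the bend for atom i then (for i >= 4) its
  # torsion; coordinate ids are what matter, order of list is cosmetic.
  if (has_rotors) {
    for (end in c(1L, n_heavy)) {
      ti <- length(coords) + 1L
      coords[[ti]] <- if (torsion == "butane")
        make_coord("torsion", "cosine", list(coef = rotor_coef))
      else make_coord("torsion", "harmonic", list(k = k_rotor, q0 = pi))
      if (end == 1L) {
        zmat[[n_heavy + 1L]] <- list(j = 1L, k = 2L, l = 3L,
                                     bond = bond_rotor,
                                     angle_fixed = theta_fix, dihedral = ti)
      } else {
        zmat[[n_heavy + 2L]] <- list(j = n_heavy, k = n_heavy - 1L,
                                     l = n_heavy - 2L, bond = bond_rotor,
                                     angle_fixed = theta_fix, dihedral = ti)
      }
    }
  }

  n_b <- max(n_heavy - 2L, 0L)
  n_backbone <- max(n_heavy - 3L, 0L)
  n_dihedrals <- n_backbone + if (has_rotors) 2L else 0L
  model <- structure(list(
    name = if (torsion == "butane") "butane-like" else "harmonic-chain",
    n_heavy = n_heavy, masses = masses, zmat = zmat, coords = coords,
    k_bond = k_bond, k_fix = k_fix,
    topology = list(n_dihedrals = n_dihedrals, n_libration = 0L),
    ground_truth = list(n_b = n_b, n_torsions = n_dihedrals,
                        n_backbone = n_backbone,
                        N_internal = n_b + n_dihedrals,
                        n_in = n_dihedrals)),
    class = "qge_toy")
  model$potential <- make_cartesian_potential(model)
  model
}

#' Butane-like toy model
#'
#' Four-atom united-atom chain with one multi-well backbone torsion, two
#' single-well methyl-like rotor torsions and two harmonic bends — the
#' synthetic analogue of n-butane with constrained bond lengths
#' (`n_in = 3`, `n_b = 2`).
#'
#' @param ... Passed to [build_chain_model()] (with `n_heavy = 4`).
#' @return A `"qge_toy"` model.
#' @export
build_butane_like <- function(...) build_chain_model(n_heavy = 4, ...)

#' @export
print.qge_toy <- function(x, ...) {
  cat(sprintf("qge_toy '%s': %d atoms, %d sampled coordinates (%d bends + %d torsions)\n",
              x$name, length(x$masses), length(x$coords),
              x$ground_truth$n_b, x$ground_truth$n_torsions))
  invisible(x)
}

# default internal coordinates (all at the potential minima)
model_qmin <- function(model) vapply(model$coords, `[[`, numeric(1), "qmin")

#' Reconstruct Cartesian coordinates from internal coordinates
#'
#' @param model A `"qge_toy"`.
#' @param q Sampled internal coordinates (bends/torsions), in model order;
#'   defaults to the potential minima.
#' @return `n_atoms x 3` coordinate matrix (nm).
#' @export
toy_coordinates <- function(model, q = model_qmin(model)) {
  stopifnot(length(q) == length(model$coords))
  n <- length(model$masses)
  x <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    z <- model$zmat[[i]]
    if (i == 2L) {
      x[2, ] <- c(z$bond, 0, 0)
    } else if (is.null(z$l)) {   # atom 3: in-plane placement
      ang <- q[z$angle]
      B <- x[z$j, ]; A <- x[z$k, ]
      u <- (A - B) / sqrt(sum((A - B)^2))
      # rotate u by ang in the xy-plane
      rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      x[i, 1:2] <- B[1:2] + z$bond * (rot %*% u[1:2])
      x[i, 3] <- 0
    } else {
      ang <- if (!is.null(z$angle_fixed)) z$angle_fixed else q[z$angle]
      x[i, ] <- place_atom(x[z$l, ], x[z$k, ], x[z$j, ], z$bond, ang,
                           q[z$dihedral])
    }
  }
  x
}

# internal-coordinate energies (vectorized over a coordinate matrix,
# rows = samples)
internal_energy <- function(model, qmat) {
  qmat <- if (is.matrix(qmat)) qmat else matrix(qmat, nrow = 1)
  U_bend <- numeric(nrow(qmat))
  U_tors <- numeric(nrow(qmat))
  for (ci in seq_along(model$coords)) {
    cc <- model$coords[[ci]]
    u <- cc$U(qmat[, ci])
    if (cc$type == "bend") U_bend <- U_bend + u else U_tors <- U_tors + u
  }
  list(U_bend = U_bend, U_pot = U_bend + U_tors)
}

# Cartesian potential evaluator consistent with the reconstruction: stiff
# springs on the constrained bonds and fixed rotor angles, the sampled
# bending/torsional potentials on the corresponding internal coordinates.
make_cartesian_potential <- function(model) {
  force(model)
  function(coords) {
    coords <- as.matrix(coords)
    U <- 0
    for (i in seq_along(model$zmat)[-1]) {
      z <- model$zmat[[i]]
      if (is.null(z)) next
      r <- sqrt(sum((coords[i, ] - coords[z$j, ])^2))
      U <- U + 0.5 * model$k_bond * (r - z$bond)^2
      if (!is.null(z$angle_fixed)) {
        th <- bond_angle(coords, if (is.null(z$k)) 1L else z$k, z$j, i)
        U <- U + 0.5 * model$k_fix * (th - z$angle_fixed)^2
      } else if (!is.null(z$angle)) {
        th <- bond_angle(coords, z$k, z$j, i)
        U <- U + model$coords[[z$angle]]$U(th)
      }
      if (!is.null(z$dihedral)) {
        ph <- dihedral_angle(coords, z$l, z$k, z$j, i)
        U <- U + model$coords[[z$dihedral]]$U(ph)
      }
    }
    U
  }
}

# ---- Metropolis sampler -------------------------------------------------

#' Sampler configuration
#'
#' @param temperature Temperature (K).
#' @param steps Metropolis sweeps after burn-in.
#' @param burnin Discarded initial sweeps (default `steps %/% 10`).
#' @param thin Keep every `thin`-th sweep (default 10).
#' @param widths Per-coordinate proposal half-widths (rad); default 0.15 for
#'   bends and 0.6 for torsions, scaled by `sqrt(T/300)`.
#' @param jump_prob Probability that a torsion proposal is an independent
#'   uniform draw over (-pi, pi] instead of a local step (default 0.2); the
#'   uniform proposal is symmetric, so detailed balance is preserved, and it
#'   lets the chain hop between torsional wells whose barriers local steps
#'   rarely cross at low temperature.
#' @param seed Mandatory RNG seed.
#' @return List of class `"sampler_config"`.
#' @export
sampler_config <- function(temperature, steps = 1e5,
                           burnin = max(1000, steps %/% 10), thin = 10,
                           widths = NULL, jump_prob = 0.2, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(temperature > 0, steps >= 1, burnin >= 0, thin >= 1,
            jump_prob >= 0, jump_prob <= 1)
  structure(list(temperature = temperature, steps = as.integer(steps),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 widths = widths, jump_prob = jump_prob,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Metropolis sampling of a toy model
#'
#' Boltzmann sampling of the model's internal coordinates (bends and
#' torsions; bonds and rotor angles fixed by construction) by
#' single-sweep Metropolis with uniform proposals, one acceptance decision
#' per coordinate per sweep (the potential is separable).  Cartesian frames
#' are reconstructed for the thinned sweeps; per-frame total and bending
#' potential energies are recorded.  Identical seeds give identical
#' trajectories.
#'
#' @param model A `"qge_toy"` model.
#' @param config A [sampler_config()].
#' @return A [trajectory()]; `metadata` records the seed, acceptance rates
#'   and the internal-coordinate samples (`metadata$q`).
#' @export
mc_sample <- function(model, config) {
  stopifnot(inherits(model, "qge_toy"), inherits(config, "sampler_config"))
  nc <- length(model$coords)
  if (nc == 0) stop("model has no sampled coordinates")
  T <- config$temperature
  beta <- 1 / (.kB_kJ * T)
  types <- vapply(model$coords, `[[`, character(1), "type")
  periodic <- vapply(model$coords, `[[`, logical(1), "periodic")
  w <- config$widths
  if (is.null(w)) w <- ifelse(types == "bend", 0.15, 0.6) * sqrt(T / 300)
  if (length(w) == 1) w <- rep(w, nc)
  set.seed(config$seed)
  q <- model_qmin(model)
  u <- vapply(seq_len(nc), function(i) model$coords[[i]]$U(q[i]), numeric(1))
  total <- config$burnin + config$steps
  keep <- seq(config$burnin + config$thin, total, by = config$thin)
  qs <- matrix(0, length(keep), nc)
  acc <- numeric(nc)
  ki <- 1L
  jp <- if (is.null(config$jump_prob)) 0.2 else config$jump_prob
  for (s in seq_len(total)) {
    prop <- q + stats::runif(nc, -w, w)
    if (jp > 0 && any(periodic)) {
      jump <- periodic & (stats::runif(nc) < jp)
      prop[jump] <- stats::runif(sum(jump), -pi, pi)
    }
    prop[periodic] <- ((prop[periodic] + pi) %% (2 * pi)) - pi
    bad <- !periodic & (prop <= 0 | prop >= pi)
    up <- vapply(seq_len(nc), function(i) model$coords[[i]]$U(prop[i]),
                 numeric(1))
    up[bad] <- Inf
    accept <- stats::runif(nc) < exp(-beta * (up - u))
    q[accept] <- prop[accept]
    u[accept] <- up[accept]
    if (s > config$burnin) acc <- acc + accept
    if (ki <= length(keep) && s == keep[ki]) {
      qs[ki, ] <- q
      ki <- ki + 1L
    }
  }
  acc <- acc / config$steps
  if (all(acc == 0)) stop("zero acceptance after burn-in; check widths/model")
  en <- internal_energy(model, qs)
  nf <- nrow(qs)
  coords <- array(0, c(nf, length(model$masses), 3))
  for (f in seq_len(nf)) coords[f, , ] <- toy_coordinates(model, qs[f, ])
  trajectory(coords, U_pot = en$U_pot, U_bend = en$U_bend, T = T,
             masses = model$masses,
             metadata = list(seed = config$seed, sampler = "metropolis",
                             acceptance = acc, q = qs,
                             model = model$name))
}

#' Simulate method for toy models
#'
#' `simulate(model, ...)` draws one or more Metropolis trajectories from the
#' toy model's Boltzmann distribution.
#'
#' @param object A `"qge_toy"` model.
#' @param nsim Number of trajectories.
#' @param seed RNG seed (mandatory; trajectory `i` uses `seed + i - 1`).
#' @param temperature Temperature (K).
#' @param ... Passed to [sampler_config()].
#' @return A [trajectory()] if `nsim = 1`, else a list of them.
#' @export
simulate.qge_toy <- function(object, nsim = 1, seed = NULL,
                             temperature = 300, ...) {
  if (is.null(seed)) stop("a seed is mandatory")
  out <- lapply(seq_len(nsim), function(i) {
    mc_sample(object, sampler_config(temperature = temperature,
                                     seed = seed + i - 1, ...))
  })
  if (nsim == 1) out[[1]] else out
}

# ---- oracles ------------------------------------------------------------

#' Brute-force quadrature oracle for a toy model
#'
#' Boltzmann-weighted 1-D quadrature over each sampled internal coordinate
#' of a separable toy model: mean potential energy (full and restricted to a
#' `+/- k sigma` box on the torsions), the in-box probability, and the
#' temperature derivative of the mean potential energy (central difference
#' at `T +/- dT`).  The per-torsion box half-width is
#' `k * sqrt(kB T / V''(qmin))`, the classical harmonic sigma of the
#' internal coordinate (equivalent to the mass-weighted mode sigma for an
#' uncoupled coordinate).
#'
#' @param model A `"qge_toy"`.
#' @param T Temperature (K).
#' @param k Box half-width multiplier (optional; no box quantities if
#'   `NULL`).
#' @param n_grid Grid points per coordinate (default 4001).
#' @param dT Temperature step for the derivative (K).
#' @param modes,min_coords Optional [normal_modes()] output and minimized
#'   structure.  When supplied (with `k`), the in-box probability is
#'   computed for the method's actual reference region — the `+/- k sigma`
#'   box on the mass-weighted semi-classical mode projections — by direct
#'   grid quadrature over the torsion coordinates (bends frozen at their
#'   minima), instead of the uncoupled per-coordinate product.  This is the
#'   appropriate reference when the semi-classical modes mix several
#'   torsions (e.g. symmetry-degenerate rotors).
#' @param n_grid_box Grid points per torsion for the mode-box quadrature.
#' @param box_half Optional explicit per-torsion box half-widths (rad),
#'   overriding `k * sigma` in the uncoupled path (e.g. to integrate a whole
#'   well up to its barrier).
#' @return List: `mean_U` (kJ/mol), `dU_dT` (kJ/mol/K), `mean_U_bend`,
#'   and when `k` given `P_in` (mode-box quadrature when `modes` supplied,
#'   else the uncoupled product), `P_per_coord`, `mean_U_in`
#'   (box-conditional mean), `sigma_q` (per-torsion half-width basis).
#' @export
quadrature_oracle <- function(model, T, k = NULL, n_grid = 4001, dT = 0.5,
                              modes = NULL, min_coords = NULL,
                              n_grid_box = 41, box_half = NULL) {
  stopifnot(inherits(model, "qge_toy"), T > 0)
  nc <- length(model$coords)
  if (nc > 8) stop("too many coordinates for quadrature; use MC instead")
  beta <- function(TT) 1 / (.kB_kJ * TT)

  coord_stats <- function(cc, TT, half = NULL) {
    if (cc$periodic) {
      q <- seq(-pi, pi, length.out = n_grid + 1)[-(n_grid + 1)]
      dist <- abs(((q - cc$qmin + pi) %% (2 * pi)) - pi)
    } else {
      q <- seq(max(1e-3, cc$qmin - 1.2), min(pi - 1e-3, cc$qmin + 1.2),
               length.out = n_grid)
      dist <- abs(q - cc$qmin)
    }
    u <- cc$U(q)
    w <- exp(-beta(TT) * (u - min(u)))
    Z <- sum(w)
    meanU <- sum(u * w) / Z
    out <- list(meanU = meanU)
    if (!is.null(half)) {
      sel <- dist <= half
      out$P <- sum(w[sel]) / Z
      out$meanU_in <- if (any(sel)) sum(u[sel] * w[sel]) / sum(w[sel]) else NA
    }
    out
  }

  halves <- rep(list(NULL), nc)
  if (!is.null(k) || !is.null(box_half)) {
    if (is.null(k)) k <- NA
    ti <- 0L
    for (i in seq_len(nc)) {
      cc <- model$coords[[i]]
      if (cc$type == "torsion") {
        ti <- ti + 1L
        halves[[i]] <- if (!is.null(box_half))
          box_half[min(ti, length(box_half))]
        else k * sqrt(.kB_kJ * T / cc$curvature)
      }
    }
  }
  st <- lapply(seq_len(nc), function(i)
    coord_stats(model$coords[[i]], T, halves[[i]]))
  types <- vapply(model$coords, `[[`, character(1), "type")
  mean_U <- sum(vapply(st, `[[`, numeric(1), "meanU"))
  mean_U_bend <- sum(vapply(which(types == "bend"), function(i)
    st[[i]]$meanU, numeric(1)))
  up <- sum(vapply(seq_len(nc), function(i)
    coord_stats(model$coords[[i]], T + dT)$meanU, numeric(1)))
  dn <- sum(vapply(seq_len(nc), function(i)
    coord_stats(model$coords[[i]], T - dT)$meanU, numeric(1)))
  res <- list(mean_U = mean_U, mean_U_bend = mean_U_bend,
              dU_dT = (up - dn) / (2 * dT))
  if (!is.null(k)) {
    tors <- which(types == "torsion")
    res$P_per_coord <- vapply(tors, function(i) st[[i]]$P, numeric(1))
    res$P_in <- prod(res$P_per_coord)
    res$mean_U_in <- sum(vapply(seq_len(nc), function(i) {
      if (types[i] == "torsion") st[[i]]$meanU_in else st[[i]]$meanU
    }, numeric(1)))
    res$sigma_q <- vapply(tors, function(i)
      sqrt(.kB_kJ * T / model$coords[[i]]$curvature), numeric(1))
    if (!is.null(modes) && !is.na(k)) {
      if (is.null(min_coords)) min_coords <- modes$min_coords
      box <- mode_box_quadrature(model, T, k, modes, min_coords,
                                 n_grid_box)
      res$P_per_coord_uncoupled <- res$P_per_coord
      res$P_in_uncoupled <- res$P_in
      res$P_in <- box$P_in
      res$mean_U_in <- box$mean_U_tors_in +
        sum(vapply(which(types == "bend"), function(i) st[[i]]$meanU,
                   numeric(1)))
    }
  }
  res
}

# Deterministic quadrature of the Boltzmann weight over the torsion
# coordinates, restricted to the mode-space +/- k sigma box: geometries are
# reconstructed on the grid (bends at their minima), superposed onto the
# minimum structure and projected on the semi-classical eigenvectors exactly
# as pref_estimate does.
mode_box_quadrature <- function(model, T, k, modes, min_coords, n_grid) {
  types <- vapply(model$coords, `[[`, character(1), "type")
  tors <- which(types == "torsion")
  if (length(tors) > 3) stop("mode-box quadrature supports <= 3 torsions")
  grids <- lapply(tors, function(i) {
    g <- seq(-pi, pi, length.out = n_grid + 1)[-(n_grid + 1)]
    u <- model$coords[[i]]$U(g)
    list(q = g, w = exp(-(u - min(u)) / (.kB_kJ * T)), u = u)
  })
  idx <- which(modes$classification == "semi-classical")
  V <- modes$eigenvectors[, idx, drop = FALSE]
  sig <- mode_sigma(modes$nu_cl, T)
  sm <- sqrt(rep(model$masses, 3))
  ref_flat <- as.vector(min_coords)
  qbase <- model_qmin(model)
  combos <- as.matrix(expand.grid(lapply(grids, function(g)
    seq_along(g$q))))
  wtot <- 0; win <- 0; wU_in <- 0
  for (r in seq_len(nrow(combos))) {
    qq <- qbase
    w <- 1; utors <- 0
    for (j in seq_along(tors)) {
      gi <- combos[r, j]
      qq[tors[j]] <- grids[[j]]$q[gi]
      w <- w * grids[[j]]$w[gi]
      utors <- utors + grids[[j]]$u[gi]
    }
    x <- superpose(toy_coordinates(model, qq), min_coords, model$masses)
    pr <- crossprod(V, (as.vector(x) - ref_flat) * sm)
    wtot <- wtot + w
    if (all(abs(pr) <= k * sig)) {
      win <- win + w
      wU_in <- wU_in + w * utors
    }
  }
  list(P_in = win / wtot,
       mean_U_tors_in = if (win > 0) wU_in / win else NA_real_)
}

#' Closed-form harmonic oracle
#'
#' Exact Gaussian results for `n` independent harmonic modes: the in-box
#' probability `erf(k/sqrt(2))^n`, the untruncated mean potential energy
#' `(n/2) kB T` and the box-conditional mean potential energy per mode,
#' `kB T/2 * (1 - 2 k phi(k) / (2 Phi(k) - 1))`.
#'
#' @param n Number of modes (or a frequency vector, whose length is used).
#' @param T Temperature (K).
#' @param k Box half-width multiplier.
#' @return List: `P_ref`, `mean_U` (kJ/mol), `mean_U_in` (kJ/mol).
#' @export
harmonic_oracle <- function(n, T, k) {
  if (length(n) > 1) n <- length(n)
  stopifnot(n >= 0, T > 0, k > 0)
  p1 <- 2 * stats::pnorm(k) - 1          # erf(k/sqrt(2))
  frac <- 1 - 2 * k * stats::dnorm(k) / p1
  list(P_ref = p1^n,
       mean_U = n / 2 * .kB_kJ * T,
       mean_U_in = n / 2 * .kB_kJ * T * frac)
}
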