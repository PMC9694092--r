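# Everything between a trajectory and the excess-difference anchors:
# essential-dynamics reference-basin selection, minimization, mass-weighted
# normal modes, quantum/semi-classical classification, frame projection,
# P_ref estimation in the +/- k sigma box, and the k-selection criterion.

#' Trajectory container
#'
#' Frames of coordinates plus per-frame total and bending potential energies
#' at one simulation temperature.
#'
#' @param coords `frames x atoms x 3` array (nm).
#' @param U_pot Per-frame total potential energy (kJ/mol).
#' @param U_bend Per-frame bending potential energy (kJ/mol); optional.
#' @param T Simulation temperature (K).
#' @param masses Atomic masses (amu).
#' @param metadata List (seed, sampler, acceptance, ...).
#' @return Object of class `"qge_trajectory"`.
#' @export
trajectory <- function(coords, U_pot, U_bend = NULL, T, masses,
                       metadata = list()) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  nf <- dim(coords)[1]
  if (length(U_pot) != nf)
    stop("U_pot length (", length(U_pot), ") != frame count (", nf, ")")
  if (!is.null(U_bend) && length(U_bend) != nf)
    stop("U_bend length (", length(U_bend), ") != frame count (", nf, ")")
  if (any(!is.finite(coords)) || any(!is.finite(U_pot)) ||
      (!is.null(U_bend) && any(!is.finite(U_bend))))
    stop("trajectory contains non-finite values")
  stopifnot(T > 0, length(masses) == dim(coords)[2], all(masses > 0))
  structure(list(coords = coords, U_pot = as.numeric(U_pot),
                 U_bend = if (is.null(U_bend)) NULL else as.numeric(U_bend),
                 T = T, masses = as.numeric(masses), metadata = metadata),
            class = "qge_trajectory")
}

#' @export
print.qge_trajectory <- function(x, ...) {
  cat(sprintf("qge_trajectory: %d frames, %d atoms, T = %g K\n",
              dim(x$coords)[1], dim(x$coords)[2], x$T))
  cat(sprintf("  <U_pot> = %.4g kJ/mol", mean(x$U_pot)))
  if (!is.null(x$U_bend)) cat(sprintf(", <U_bend> = %.4g kJ/mol", mean(x$U_bend)))
  cat("\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

# superpose every frame onto ref (mass-weighted); returns frames x atoms x 3
superpose_frames <- function(traj, ref_coords) {
  out <- traj$coords
  for (f in seq_len(dim(out)[1]))
    out[f, , ] <- superpose(out[f, , ], ref_coords, traj$masses)
  out
}

#' Select the reference frame by essential-dynamics analysis
#'
#' Superposes all frames onto the first frame (mass-weighted least squares),
#' diagonalizes the covariance matrix of the Cartesian coordinates, projects
#' the frames onto the two largest-variance eigenvectors (the essential
#' plane), histograms the projections on a `bins x bins` grid and returns the
#' frame closest (Euclidean distance in projection space) to the center of
#' the most populated bin.  Ties in bin population break to the lowest
#' flattened bin index; ties in distance to the lowest frame index.
#'
#' @param traj A [trajectory()], at least 2 frames.
#' @param bins Histogram grid size per axis (default 50).
#' @return List with `frame` (index), `projections` (`frames x 2`),
#'   `eigenvectors` (`3n x 2`), `bin` (chosen bin indices), `centroid`.
#' @export
select_reference_frame <- function(traj, bins = 50) {
  stopifnot(inherits(traj, "qge_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("at least 2 frames required")
  fitted <- superpose_frames(traj, traj$coords[1, , ])
  X <- matrix(fitted, nrow = nf)   # frames x 3n
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nf - 1)
  ev <- eigen(C, symmetric = TRUE)
  V <- ev$vectors[, 1:2, drop = FALSE]
  proj <- Xc %*% V
  rng <- apply(proj, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  ix <- pmin(bins, 1L + floor((proj[, 1] - rng[1, 1]) / span[1] * bins))
  iy <- pmin(bins, 1L + floor((proj[, 2] - rng[1, 2]) / span[2] * bins))
  flat <- ix + (iy - 1L) * bins
  counts <- tabulate(flat, nbins = bins * bins)
  best <- which.max(counts)            # lowest index wins ties
  bx <- ((best - 1L) %% bins) + 1L
  by <- ((best - 1L) %/% bins) + 1L
  centroid <- c(rng[1, 1] + (bx - 0.5) / bins * span[1],
                rng[1, 2] + (by - 0.5) / bins * span[2])
  d2 <- (proj[, 1] - centroid[1])^2 + (proj[, 2] - centroid[2])^2
  list(frame = which.min(d2), projections = proj, eigenvectors = V,
       eigenvalues = ev$values[1:2], bin = c(bx, by), centroid = centroid)
}

#' Energy-minimize a structure
#'
#' Local minimization of a Cartesian potential-energy evaluator starting
#' from `coords`, via BFGS on the flattened coordinates with a
#' finite-difference gradient (or an analytic one if supplied), followed by
#' Newton polishing with a finite-difference Hessian until the largest
#' gradient component falls below `gtol`.
#'
#' @param coords Starting `n x 3` coordinates (nm).
#' @param potential Function `f(coords_matrix) -> energy` (kJ/mol).
#' @param gradient Optional function `g(coords_matrix) -> n x 3` gradient
#'   (kJ/mol/nm); default central finite differences.
#' @param gtol Gradient convergence threshold (kJ/mol/nm).
#' @param maxit BFGS iteration cap.
#' @return List with `coords` (minimized), `energy` (`U_pot_ref`),
#'   `max_grad`, `converged`.
#' @export
minimize_structure <- function(coords, potential, gradient = NULL,
                               gtol = 1e-5, maxit = 2000) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  fn <- function(x) potential(matrix(x, n, 3))
  gr <- if (is.null(gradient)) {
    function(x) as.vector(num_gradient(potential, matrix(x, n, 3)))
  } else {
    function(x) as.vector(gradient(matrix(x, n, 3)))
  }
  e0 <- fn(as.vector(coords))
  res <- stats::optim(as.vector(coords), fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-15))
  x <- res$par
  # Newton polishing: small systems, finite-difference Hessian is cheap
  for (iter in 1:25) {
    g <- gr(x)
    if (max(abs(g)) < gtol) break
    H <- fd_hessian_flat(fn, x, step = 1e-5)
    # regularize in the rototranslational null space
    H <- H + diag(1e-8, length(x))
    dx <- tryCatch(solve(H, g), error = function(e) g * 0.0)
    if (all(dx == 0)) break
    xn <- x - dx
    if (fn(xn) <= fn(x) + 1e-12) x <- xn else break
  }
  g <- gr(x)
  mg <- max(abs(g))
  out <- list(coords = matrix(x, n, 3), energy = fn(x), max_grad = mg,
              converged = mg < gtol, start_energy = e0)
  if (!out$converged)
    stop(structure(class = c("qge_minimization_error", "error", "condition"),
                   list(message = sprintf(
                     "minimization did not converge (max |grad| = %.3g)", mg),
                     call = sys.call(-1), state = out)))
  out
}

# finite-difference Hessian of fn on a flat coordinate vector
fd_hessian_flat <- function(fn, x, step = 1e-4) {
  m <- length(x)
  H <- matrix(0, m, m)
  g_at <- function(y) {
    g <- numeric(m)
    for (j in seq_len(m)) {
      yp <- y; yp[j] <- yp[j] + step
      ym <- y; ym[j] <- ym[j] - step
      g[j] <- (fn(yp) - fn(ym)) / (2 * step)
    }
    g
  }
  for (j in seq_len(m)) {
    xp <- x; xp[j] <- xp[j] + step
    xm <- x; xm[j] <- xm[j] - step
    H[, j] <- (g_at(xp) - g_at(xm)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Mass-weighted normal modes at a minimum
#'
#' Central-finite-difference Hessian of the potential at `coords`,
#' mass-weighted, with the exact translation/rotation generators projected
#' out before diagonalization.  Modes with |wavenumber| below `rt_thresh`
#' are classified roto-translational; of the remaining (ascending) internal
#' modes the `n_in` lowest are semi-classical, the rest quantum.
#'
#' @param coords Minimum-energy `n x 3` coordinates (nm); the gradient should
#'   be negligible there.
#' @param masses Masses (amu).
#' @param potential Cartesian energy function (kJ/mol).
#' @param n_in Number of semi-classical internal modes (default 0).
#' @param step Finite-difference step per Cartesian coordinate (nm).
#' @param rt_thresh Roto-translational wavenumber threshold (cm^-1).
#' @return Object of class `"mode_set"`: `frequencies` (cm^-1, ascending,
#'   internal modes only), `eigenvectors` (`3n x n_modes`, mass-weighted,
#'   orthonormal), `classification`, `n_in`, `nu_cl`, `nu_q`, `masses`,
#'   `min_coords`.
#' @export
normal_modes <- function(coords, masses, potential, n_in = 0,
                         step = 1e-4, rt_thresh = 1.0) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(masses) == n)
  fn <- function(x) potential(matrix(x, n, 3))
  H <- fd_hessian_flat(fn, as.vector(coords), step = step)
  sm <- sqrt(rep(masses, times = 3))   # flattening is column-major: x then y then z
  # NOTE: as.vector(matrix) flattens column-major, i.e. all x, all y, all z;
  # masses repeat accordingly.
  Hmw <- H / outer(sm, sm)
  P <- rt_projector(coords, masses)
  Hp <- P %*% Hmw %*% P
  Hp <- (Hp + t(Hp)) / 2
  ev <- eigen(Hp, symmetric = TRUE)
  lam <- rev(ev$values)                       # ascending
  vec <- ev$vectors[, rev(seq_len(ncol(ev$vectors))), drop = FALSE]
  # lam in ps^-2 -> wavenumber cm^-1 (signed for negative curvature)
  wn <- sign(lam) * sqrt(abs(lam)) * 1e12 / (2 * pi) / .c_cm
  is_rt <- abs(wn) < rt_thresh
  if (any(wn < -rt_thresh))
    stop("not a minimum: imaginary frequency ",
         paste(signif(wn[wn < -rt_thresh], 4), collapse = ", "), " cm^-1")
  n_rt <- sum(is_rt)
  if (n_rt < 5 || n_rt > 6)
    warning("expected 6 roto-translational modes (5 if linear), found ", n_rt)
  keep <- which(!is_rt)
  wn_int <- wn[keep]
  vec_int <- vec[, keep, drop = FALSE]
  o <- order(wn_int)
  wn_int <- wn_int[o]
  vec_int <- vec_int[, o, drop = FALSE]
  if (n_in > length(wn_int)) stop("n_in exceeds the number of internal modes")
  cls <- rep("quantum", length(wn_int))
  if (n_in > 0) cls[seq_len(n_in)] <- "semi-classical"
  structure(list(frequencies = wn_int, eigenvectors = vec_int,
                 classification = cls, n_in = n_in,
                 nu_cl = wn_int[cls == "semi-classical"],
                 nu_q = wn_int[cls == "quantum"],
                 n_rototrans = n_rt, masses = as.numeric(masses),
                 min_coords = coords),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d internal modes (%d semi-classical, %d quantum), %d roto-translational removed\n",
              length(x$frequencies), sum(x$classification == "semi-classical"),
              sum(x$classification == "quantum"), x$n_rototrans))
  cat("  frequencies (cm^-1):",
      paste(signif(x$frequencies, 4), collapse = ", "), "\n")
  invisible(x)
}

# projector onto the complement of the mass-weighted translation/rotation
# generators (column-major flattening: all x, all y, all z)
rt_projector <- function(coords, masses) {
  n <- nrow(coords)
  sm <- sqrt(masses)
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2, com)
  gens <- matrix(0, 3 * n, 6)
  for (a in 1:3) {
    v <- matrix(0, n, 3); v[, a] <- sm
    gens[, a] <- as.vector(v)
  }
  axes <- diag(3)
  for (a in 1:3) {
    v <- sm * t(apply(r, 1, function(ri) c(
      axes[a, 2] * ri[3] - axes[a, 3] * ri[2],
      axes[a, 3] * ri[1] - axes[a, 1] * ri[3],
      axes[a, 1] * ri[2] - axes[a, 2] * ri[1])))
    gens[, 3 + a] <- as.vector(v)
  }
  # orthonormalize, dropping null generators (linear molecules)
  qr_d <- qr(gens)
  rank <- qr_d$rank
  Q <- qr.Q(qr_d)[, seq_len(rank), drop = FALSE]
  diag(3 * n) - Q %*% t(Q)
}

#' Semi-classical internal degree-of-freedom count from topology
#'
#' The semi-classical (low-frequency) internal modes are the dihedral angles
#' plus, for molecular complexes, the inter-monomer libration coordinates
#' (6 for a two-body complex).
#'
#' @param topology List with `n_dihedrals` and optionally `n_libration`
#'   (default 0), or an object with a `topology` field of that shape.
#' @return Integer `n_in`.
#' @export
count_semiclassical <- function(topology) {
  if (!is.null(topology$topology)) topology <- topology$topology
  nd <- topology$n_dihedrals
  nl <- if (is.null(topology$n_libration)) 0L else topology$n_libration
  stopifnot(!is.null(nd), nd >= 0, nl >= 0)
  as.integer(nd + nl)
}

# per-frame projections of the mass-weighted displacement from min_coords
# onto the semi-classical eigenvectors; frames superposed first by default
mode_projections <- function(traj, modes, min_coords, superpose = TRUE) {
  stopifnot(inherits(modes, "mode_set"))
  idx <- which(modes$classification == "semi-classical")
  if (!length(idx)) stop("mode set has no semi-classical modes (n_in = 0)")
  V <- modes$eigenvectors[, idx, drop = FALSE]
  sm <- sqrt(rep(traj$masses, times = 3))
  nf <- n_frames(traj)
  ref_flat <- as.vector(min_coords)
  if (!superpose) {
    # pre-aligned frames: one matrix product
    X <- matrix(traj$coords, nrow = nf)
    return(sweep(X, 2, ref_flat) %*% (V * sm))
  }
  proj <- matrix(0, nf, length(idx))
  for (f in seq_len(nf)) {
    x <- superpose(traj$coords[f, , ], min_coords, traj$masses)
    proj[f, ] <- crossprod(V, (as.vector(x) - ref_flat) * sm)
  }
  proj
}

# classical harmonic sigma of a mass-weighted mode coordinate,
# sigma^2 = kB T / (2 pi nu)^2; wavenumber cm^-1 -> nu in ps^-1
mode_sigma <- function(wavenumber, T) {
  nu_ps <- wavenumber * .c_cm * 1e-12
  sqrt(.kB_kJ * T) / (2 * pi * nu_ps)
}

#' Reference-conformation probability in the +/- k sigma box
#'
#' Superposes every frame onto the minimum-energy structure, projects the
#' mass-weighted displacement onto each semi-classical eigenvector and counts
#' the frames with all `n_in` projections inside `+/- k sigma_j,cl`
#' simultaneously, where `sigma_j,cl^2 = kB T0 / (2 pi nu_j,cl)^2` is the
#' classical harmonic variance of the mode coordinate.
#'
#' @param traj [trajectory()] at `T0`.
#' @param modes [normal_modes()] output with `n_in >= 1`.
#' @param min_coords Minimum-energy structure (`n x 3`, nm).
#' @param k Box half-width multiplier (positive integer).
#' @param T0 Temperature (K); defaults to `traj$T`.
#' @param superpose Superpose frames before projecting (default `TRUE`; set
#'   `FALSE` for pre-aligned synthetic frames).
#' @return Object of class `"pref_estimate"`: `k`, `sigma`, `n_inside`,
#'   `n_frames`, `Pref`, `se` (block-averaged), `inside` (logical vector),
#'   `projections`.
#' @export
pref_estimate <- function(traj, modes, min_coords, k, T0 = traj$T,
                          superpose = TRUE) {
  stopifnot(k >= 1, abs(k - round(k)) < 1e-9)
  proj <- mode_projections(traj, modes, min_coords, superpose = superpose)
  sigma <- mode_sigma(modes$nu_cl, T0)
  inside <- rowSums(abs(proj) <= rep(k * sigma, each = nrow(proj))) ==
    ncol(proj)
  nf <- nrow(proj)
  Pref <- mean(inside)
  if (Pref == 0)
    stop("P_ref is zero: no frames inside the reference box; ",
         "lengthen the sampling or reduce k")
  se <- if (nf >= 16) block_se(as.numeric(inside))
        else sqrt(Pref * (1 - Pref) / nf)
  structure(list(k = k, sigma = sigma, n_inside = sum(inside),
                 n_frames = nf, Pref = Pref, se = se, inside = inside,
                 projections = proj),
            class = "pref_estimate")
}

#' @export
print.pref_estimate <- function(x, ...) {
  cat(sprintf("P_ref = %.4g +/- %.2g  (k = %d, %d / %d frames inside)\n",
              x$Pref, x$se, x$k, x$n_inside, x$n_frames))
  invisible(x)
}

#' Select the box multiplier k by the equipartition criterion
#'
#' For each candidate `k` the mean potential energy over the in-box frames,
#' `<U_pot>_ref,0`, is compared with the harmonic expectation
#' `U_pot,ref + (N/2) kB T0`; a `k` passes at a confidence level if the
#' deviation is within `z` standard errors (`z = 2`: 95 percent, `z = 3`:
#' 99.9 percent) of `<U_pot>_ref,0`.  The chosen `k` at each level is the
#' largest passing one.
#'
#' @param traj [trajectory()] at `T0`.
#' @param modes [normal_modes()] output.
#' @param min_coords Minimum-energy structure.
#' @param N Number of internal degrees of freedom (dihedrals + unconstrained
#'   bendings).
#' @param T0 Temperature (K); defaults to `traj$T`.
#' @param U_pot_ref Potential energy of the reference minimum (kJ/mol).
#' @param k_max Largest candidate `k`.
#' @param superpose Passed to [pref_estimate()].
#' @return Object of class `"k_report"`: data.frame `table` with per-k rows
#'   (`k`, `Pref`, `mean_U_ref`, `dev` = deviation from the harmonic target,
#'   `target`, `se`, `pass95`, `pass999`) and `chosen` (named vector, `NA`
#'   when no k passes).
#' @export
select_k <- function(traj, modes, min_coords, N, T0 = traj$T, U_pot_ref,
                     k_max = 10, superpose = TRUE) {
  stopifnot(N >= 1, k_max >= 1)
  target <- N / 2 * .kB_kJ * T0
  proj <- mode_projections(traj, modes, min_coords, superpose = superpose)
  sigma <- mode_sigma(modes$nu_cl, T0)
  rows <- lapply(seq_len(k_max), function(k) {
    inside <- rowSums(abs(proj) <= rep(k * sigma, each = nrow(proj))) ==
      ncol(proj)
    n_in_box <- sum(inside)
    if (n_in_box == 0)
      return(data.frame(k = k, Pref = 0, mean_U_ref = NA_real_,
                        dev = NA_real_, target = target, se = NA_real_,
                        pass95 = FALSE, pass999 = FALSE))
    u <- traj$U_pot[inside]
    m <- mean(u)
    se <- if (n_in_box >= 16) block_se(u) else stats::sd(u) / sqrt(n_in_box)
    dev <- m - U_pot_ref - target
    data.frame(k = k, Pref = n_in_box / nrow(proj), mean_U_ref = m,
               dev = dev, target = target, se = se,
               pass95 = is.finite(se) && abs(dev) <= 2 * se,
               pass999 = is.finite(se) && abs(dev) <= 3 * se)
  })
  tab <- do.call(rbind, rows)
  pick <- function(col) {
    ok <- tab$k[tab[[col]]]
    if (length(ok)) max(ok) else NA_integer_
  }
  structure(list(table = tab,
                 chosen = c(k95 = pick("pass95"), k999 = pick("pass999")),
                 N = N, T0 = T0, U_pot_ref = U_pot_ref),
            class = "k_report")
}

#' @export
print.k_report <- function(x, ...) {
  cat(sprintf("k selection (N = %d, T0 = %g K, target = %.4g kJ/mol):\n",
              x$N, x$T0, x$table$target[1]))
  print(format(x$table, digits = 4), row.names = FALSE)
  cat(sprintf("chosen k: %s (95%%), %s (99.9%%)\n",
              x$chosen["k95"], x$chosen["k999"]))
  invisible(x)
}

#' Block-averaging standard error of the mean
#'
#' Standard error of a (possibly autocorrelated) series by block averaging
#' with doubling block sizes; the estimate is taken at the plateau where
#' doubling the block size no longer increases the SE appreciably.  For
#' uncorrelated data this reduces to the naive `sd/sqrt(n)`.
#'
#' @param x Numeric series, at least 16 samples.
#' @param min_blocks Minimum number of blocks retained (default 8).
#' @return Standard error of the mean.
#' @export
block_se <- function(x, min_blocks = 8) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16) stop("block_se needs at least 16 samples")
  if (stats::sd(x) == 0) return(0)
  sizes <- 2^(0:floor(log2(n / min_blocks)))
  ses <- vapply(sizes, function(b) {
    nb <- n %/% b
    bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    stats::sd(bm) / sqrt(nb)
  }, numeric(1))
  for (i in seq_along(ses)[-length(ses)]) {
    if (ses[i + 1] < ses[i] * 1.02) return(ses[i])
  }
  ses[length(ses)]
}
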