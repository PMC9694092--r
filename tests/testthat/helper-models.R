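# Shared fixtures, built once per test run and cached.

kB_kJ <- 1.380649e-23 * 6.02214076e23 / 1000   # molar, kJ/(mol K)
R_J <- kB_kJ * 1000

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# butane-like toy with minimized structure and modes
butane_setup <- function() {
  cached("butane", {
    m <- build_butane_like()
    minim <- minimize_structure(toy_coordinates(m), m$potential)
    modes <- normal_modes(minim$coords, m$masses, m$potential, n_in = 3)
    list(model = m, minim = minim, modes = modes)
  })
}

# fully harmonic chain with minimized structure and modes
harmonic_setup <- function() {
  cached("harmonic", {
    m <- build_chain_model(4, torsion = "harmonic")
    minim <- minimize_structure(toy_coordinates(m), m$potential)
    modes <- normal_modes(minim$coords, m$masses, m$potential, n_in = 3)
    list(model = m, minim = minim, modes = modes)
  })
}

# reference trajectory of the butane-like toy at 200 K (the T0 run is
# 2.5x longer than the temperature-series runs, as the reference protocol
# prescribes)
butane_ref_traj <- function() {
  cached("butane_ref", {
    s <- butane_setup()
    mc_sample(s$model, sampler_config(200, steps = 2.5e5, seed = 2026))
  })
}

# a random proper rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# frames sampled exactly from the Gaussian distribution of the given modes
# (mass-weighted displacements along the semi-classical eigenvectors)
exact_mode_frames <- function(setup, T0, n_frames, seed) {
  set.seed(seed)
  modes <- setup$modes
  masses <- setup$model$masses
  idx <- which(modes$classification == "semi-classical")
  V <- modes$eigenvectors[, idx, drop = FALSE]
  sig <- sqrt(kB_kJ * T0) / (2 * pi * modes$nu_cl * 2.99792458e10 * 1e-12)
  sm <- sqrt(rep(masses, 3))
  C <- matrix(stats::rnorm(n_frames * length(idx)), n_frames) %*% diag(sig)
  D <- C %*% t(V)
  ref <- as.vector(setup$minim$coords)
  coords <- array(0, c(n_frames, length(masses), 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- matrix(ref + D[f, ] / sm, length(masses), 3)
  trajectory(coords, U_pot = numeric(n_frames), T = T0, masses = masses)
}
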