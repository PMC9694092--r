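# Essential dynamics, minimization, normal modes, P_ref and k selection.

test_that("essential dynamics picks the dominant basin", {
  set.seed(21)
  masses <- c(12, 12, 12, 12)
  base <- matrix(runif(12, -0.2, 0.2), 4, 3)
  # a genuinely different conformation (not a rigid motion of `base`)
  far <- base
  far[4, ] <- far[4, ] + c(0.35, -0.25, 0.2)
  far[1, ] <- far[1, ] - c(0.1, 0.3, 0)
  nf <- 200
  labels <- rep(c("A", "B"), c(180, 20))
  coords <- array(0, c(nf, 4, 3))
  for (f in 1:nf) {
    centre <- if (labels[f] == "A") base else far
    coords[f, , ] <- centre + matrix(rnorm(12, sd = 0.01), 4, 3)
  }
  tr <- trajectory(coords, U_pot = numeric(nf), T = 200, masses = masses)
  sel <- select_reference_frame(tr)
  expect_equal(labels[sel$frame], "A")
  # deterministic
  expect_equal(select_reference_frame(tr)$frame, sel$frame)

  # all frames identical: frame 1 by the tie-break rule
  same <- array(rep(base, each = 10), c(10, 4, 3))
  tr2 <- trajectory(same, numeric(10), T = 200, masses = masses)
  expect_equal(select_reference_frame(tr2)$frame, 1L)

  expect_error(select_reference_frame(
    trajectory(array(base, c(1, 4, 3)), 0, T = 200, masses = masses)),
    "2 frames")
})

test_that("minimization reaches analytic and scanned minima", {
  # 3-D harmonic wells with distinct centres
  centres <- matrix(c(0, 0, 0, 0.3, 0.1, -0.2, -0.1, 0.25, 0.15), 3, 3,
                    byrow = TRUE)
  pot <- function(x) sum(50 * (x - centres)^2)
  set.seed(3)
  res <- minimize_structure(centres + matrix(rnorm(9, sd = 0.05), 3, 3), pot)
  expect_equal(res$coords, centres, tolerance = 1e-6)
  expect_lte(res$energy, res$start_energy)

  # starting at the minimum: unchanged
  res0 <- minimize_structure(centres, pot)
  expect_equal(res0$coords, centres, tolerance = 1e-7)

  # butane-like toy started near gauche relaxes to the gauche minimum whose
  # torsion matches a dense 1-D scan of the backbone potential
  s <- butane_setup()
  m <- s$model
  Uback <- m$coords[[3]]$U
  phi_grid <- seq(0.1, 2.0, length.out = 4000)   # the positive-gauche well
  phi_gauche <- phi_grid[which.min(Uback(phi_grid))]
  q <- sapply(m$coords, function(cc) cc$qmin)
  q[3] <- phi_gauche + 0.25
  resg <- minimize_structure(toy_coordinates(m, q), m$potential)
  phi_min <- qgethermo:::dihedral_angle(resg$coords, 1, 2, 3, 4)
  expect_equal(phi_min, phi_gauche, tolerance = 1e-3)
})

test_that("normal modes reproduce the diatomic closed form and invariances", {
  # diatomic with a single spring: nu = (1/2 pi) sqrt(kappa / mu_red)
  kappa <- 1e5; m1 <- 12; m2 <- 19; r0 <- 0.12
  pot <- function(x) {
    r <- sqrt(sum((x[2, ] - x[1, ])^2))
    0.5 * kappa * (r - r0)^2
  }
  coords <- rbind(c(0, 0, 0), c(r0, 0, 0))
  nm <- suppressWarnings(normal_modes(coords, c(m1, m2), pot))
  mu_red <- m1 * m2 / (m1 + m2)
  nu_oracle <- sqrt(kappa / mu_red) / (2 * pi) * 1e12 / 2.99792458e10
  expect_equal(length(nm$frequencies), 1L)
  expect_equal(nm$frequencies, nu_oracle, tolerance = 1e-4)

  # butane-like toy: exactly 6 roto-translational modes removed, 12 internal
  s <- butane_setup()
  expect_equal(s$modes$n_rototrans, 6L)
  expect_equal(length(s$modes$frequencies), 12L)
  expect_equal(s$modes$classification[1:3], rep("semi-classical", 3))
  expect_true(all(diff(s$modes$frequencies) >= 0))
  expect_true(all(s$modes$frequencies > 0))

  # rigid rotation leaves the spectrum unchanged (the potential depends
  # only on internal coordinates)
  R <- random_rotation(17)
  nm_rot <- normal_modes(s$minim$coords %*% t(R), s$model$masses,
                         s$model$potential, n_in = 3)
  expect_equal(nm_rot$frequencies, s$modes$frequencies, tolerance = 1e-4)

  # a saddle is flagged
  pot_saddle <- function(x) {
    r <- sqrt(sum((x[2, ] - x[1, ])^2))
    -0.5 * kappa * (r - r0)^2
  }
  expect_error(suppressWarnings(
    normal_modes(coords, c(m1, m2), pot_saddle)), "not a minimum")
})

test_that("P_ref estimation matches the Gaussian box law on exact samples", {
  s <- harmonic_setup()
  tr <- exact_mode_frames(s, T0 = 200, n_frames = 2e4, seed = 31)
  for (k in c(1, 2)) {
    pe <- pref_estimate(tr, s$modes, s$minim$coords, k = k,
                        superpose = FALSE)
    p1 <- 2 * pnorm(k) - 1
    expect_equal(pe$Pref, p1^3,
                 tolerance = 4 * sqrt(p1^3 * (1 - p1^3) / 2e4) / p1^3)
  }
  # monotone non-decreasing in k
  ps <- sapply(1:5, function(k)
    pref_estimate(tr, s$modes, s$minim$coords, k = k,
                  superpose = FALSE)$Pref)
  expect_true(all(diff(ps) >= 0))

  # the minimum structure itself projects to zero on every mode
  one <- trajectory(array(s$minim$coords, c(1, 6, 3)), 0, T = 200,
                    masses = s$model$masses)
  pr <- qgethermo:::mode_projections(one, s$modes, s$minim$coords)
  expect_lt(max(abs(pr)), 1e-8)

  expect_error(pref_estimate(tr, s$modes, s$minim$coords, k = 2.5), "TRUE")
})

test_that("block averaging handles constant, iid and correlated series", {
  expect_equal(block_se(rep(3.2, 100)), 0)
  expect_error(block_se(rnorm(10)), "16 samples")

  # iid normal: close to sigma/sqrt(n) on average over seeds
  n <- 1024; sds <- numeric(20)
  set.seed(12)
  for (i in 1:20) sds[i] <- block_se(rnorm(n, sd = 2))
  expect_gt(mean(sds), 0.7 * 2 / sqrt(n))
  expect_lt(mean(sds), 1.3 * 2 / sqrt(n))

  # positively correlated AR(1): block SE above the naive estimate
  set.seed(13)
  x <- as.numeric(arima.sim(list(ar = 0.9), 4096))
  expect_gt(block_se(x), sd(x) / sqrt(length(x)))
})

test_that("semi-classical counting follows the dihedral + libration rule", {
  expect_equal(count_semiclassical(list(n_dihedrals = 3)), 3L)
  expect_equal(count_semiclassical(list(n_dihedrals = 17, n_libration = 6)),
               23L)
  expect_equal(count_semiclassical(list(n_dihedrals = 0)), 0L)
  expect_equal(count_semiclassical(build_butane_like()), 3L)
})

test_that("k selection reports both confidence levels and largest passing k", {
  s <- harmonic_setup()
  tr <- cached("harm_traj_200", mc_sample(s$model,
                                          sampler_config(200, steps = 1e5,
                                                         seed = 7)))
  kr <- select_k(tr, s$modes, s$minim$coords, N = 5,
                 U_pot_ref = s$minim$energy, k_max = 6)
  expect_s3_class(kr, "k_report")
  expect_equal(nrow(kr$table), 6L)
  expect_true(all(c("pass95", "pass999") %in% names(kr$table)))
  # 99.9 percent is the more permissive level: k(95) <= k(99.9)
  expect_lte(kr$chosen["k95"], kr$chosen["k999"])
  # largest passing k is the chosen one
  expect_equal(unname(kr$chosen["k999"]), max(kr$table$k[kr$table$pass999]))
  # P_ref column is monotone in k
  expect_true(all(diff(kr$table$Pref) >= -1e-12))
})
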