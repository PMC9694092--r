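# Toy models, Metropolis sampler and the oracles.

test_that("chain builder exposes the right ground truth", {
  m4 <- build_butane_like()
  expect_equal(m4$ground_truth$n_torsions, 3L)   # 1 backbone + 2 rotors
  expect_equal(m4$ground_truth$n_b, 2L)
  expect_equal(m4$ground_truth$N_internal, 5L)
  expect_equal(count_semiclassical(m4), 3L)

  m2 <- build_chain_model(2)
  expect_equal(m2$ground_truth$n_torsions, 0L)
  expect_equal(m2$ground_truth$n_b, 0L)

  m8 <- build_chain_model(8)
  expect_equal(m8$ground_truth$n_backbone, 5L)   # n_heavy - 3
  expect_equal(m8$ground_truth$n_torsions, 7L)   # + 2 rotor terms
  expect_equal(m8$ground_truth$n_b, 6L)

  # reconstruction at the minima is the Cartesian minimum (energy ~ 0)
  expect_lt(m4$potential(toy_coordinates(m4)), 1e-10)
})

test_that("the sampler is Boltzmann-exact on a harmonic bend", {
  m <- build_chain_model(3, torsion = "harmonic")   # 1 bend + 2 rotors
  T0 <- 300
  tr <- mc_sample(m, sampler_config(T0, steps = 8e4, seed = 55))
  q <- tr$metadata$q
  bend_idx <- which(sapply(m$coords, `[[`, "type") == "bend")
  th <- q[, bend_idx]
  # equipartition: var(theta) -> kB T / k_theta
  v_expect <- kB_kJ * T0 / 520
  v_se <- block_se((th - mean(th))^2) # SE of the second-moment estimate
  expect_lt(abs(var(th) - v_expect), 3 * v_se)
  # mean bend energy kB T / 2 per bend
  expect_lt(abs(mean(tr$U_bend) - kB_kJ * T0 / 2),
            3 * block_se(tr$U_bend))
})

test_that("the sampler is reproducible and symmetric wells equilibrate", {
  m <- build_butane_like()
  t1 <- mc_sample(m, sampler_config(300, steps = 2e4, seed = 9))
  t2 <- mc_sample(m, sampler_config(300, steps = 2e4, seed = 9))
  expect_identical(t1$U_pot, t2$U_pot)
  expect_identical(t1$coords, t2$coords)
  t3 <- mc_sample(m, sampler_config(300, steps = 2e4, seed = 10))
  expect_false(identical(t1$U_pot, t3$U_pot))

  # symmetric double-well backbone: equal well populations
  md <- build_chain_model(4, backbone_coef = c("2" = 5))
  trd <- mc_sample(md, sampler_config(250, steps = 6e4, seed = 77))
  phi <- trd$metadata$q[, 3]   # the backbone torsion
  right <- as.numeric(phi > 0)
  expect_lt(abs(mean(right) - 0.5), 3 * max(block_se(right), 1e-3))
})

test_that("quadrature oracle matches closed forms and converges", {
  # harmonic torsions: in-box probability = erf(k/sqrt(2)) per coordinate
  m <- build_chain_model(3, torsion = "harmonic")
  for (k in c(1, 3)) {
    or <- quadrature_oracle(m, 250, k = k)
    expect_equal(or$P_per_coord, rep(2 * pnorm(k) - 1, 2), tolerance = 3e-3)
  }
  # grid refinement changes nothing material
  o1 <- quadrature_oracle(m, 250, k = 2, n_grid = 2001)
  o2 <- quadrature_oracle(m, 250, k = 2, n_grid = 4001)
  expect_equal(o1$P_in, o2$P_in, tolerance = 1e-3)
  expect_equal(o1$mean_U, o2$mean_U, tolerance = 1e-8)

  # as the non-reference wells rise, the reference-well probability -> 1
  # (box = the trans well up to the trans/gauche barrier, ~pi/3 away)
  shallow <- build_butane_like()
  steep <- build_butane_like(backbone_coef = 50 * c("1" = 2.9, "3" = 5.92),
                             rotor_coef = 50 * c("1" = 7.5))
  P_shallow <- quadrature_oracle(shallow, 250,
                                 box_half = pi / 3)$P_per_coord[1]
  P_steep <- quadrature_oracle(steep, 250,
                               box_half = pi / 3)$P_per_coord[1]
  expect_lt(P_shallow, 0.99)
  expect_gt(P_steep, 1 - 1e-6)

  # dU/dT of a harmonic coordinate is kB/2 per dof
  orh <- quadrature_oracle(m, 300)
  expect_equal(orh$dU_dT, 3 / 2 * kB_kJ, tolerance = 1e-3)

  expect_error(quadrature_oracle(build_chain_model(12), 300), "quadrature")
})

test_that("harmonic oracle gives the textbook Gaussian values", {
  or <- harmonic_oracle(3, 200, 3)
  expect_equal(or$P_ref, (2 * pnorm(3) - 1)^3, tolerance = 1e-12)
  expect_equal(or$P_ref, 0.9919, tolerance = 1e-4)
  expect_equal(or$mean_U, 1.5 * kB_kJ * 200, tolerance = 1e-12)
  # truncation lowers the box-conditional mean energy
  expect_lt(or$mean_U_in, or$mean_U)
  # frequency-vector input uses its length
  expect_equal(harmonic_oracle(c(50, 80, 120), 200, 3)$P_ref, or$P_ref)
})

test_that("simulate() draws trajectories from the toy model", {
  m <- build_chain_model(3, torsion = "harmonic")
  tr <- simulate(m, seed = 4, temperature = 280, steps = 5000)
  expect_s3_class(tr, "qge_trajectory")
  expect_equal(tr$T, 280)
  expect_error(simulate(m, temperature = 280, steps = 1000), "seed")
  two <- simulate(m, nsim = 2, seed = 4, temperature = 280, steps = 2000)
  expect_length(two, 2)
})
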