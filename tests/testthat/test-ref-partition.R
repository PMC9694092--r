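# Reference-conformation partition functions and anchor assembly.

test_that("principal inertia moments match analytic cases and are rotation-invariant", {
  # two masses m at (+/- d, 0, 0): (0, 2 m d^2, 2 m d^2)
  m <- 3.5; d <- 0.2
  I <- principal_inertia(rbind(c(d, 0, 0), c(-d, 0, 0)), c(m, m))
  expect_equal(I, c(0, 2 * m * d^2, 2 * m * d^2), tolerance = 1e-12)

  # equilateral triangle of unit masses, side a: (a^2/2, a^2/2, a^2)
  a <- 0.3
  r <- a / sqrt(3)
  tri <- t(sapply(0:2, function(k) r * c(cos(2 * pi * k / 3),
                                         sin(2 * pi * k / 3), 0)))
  expect_equal(principal_inertia(tri, rep(1, 3)),
               c(a^2 / 2, a^2 / 2, a^2), tolerance = 1e-12)

  # rigid rotation + translation leaves the moments unchanged
  set.seed(7)
  X <- matrix(runif(15, -0.3, 0.3), 5, 3)
  mm <- runif(5, 1, 16)
  R <- random_rotation(3)
  X2 <- sweep(X %*% t(R), 2, c(1, -2, 0.5), "+")
  expect_equal(principal_inertia(X2, mm), principal_inertia(X, mm),
               tolerance = 1e-10)

  expect_error(principal_inertia(matrix(0, 0, 3), numeric(0)), "atom")
})

test_that("roto-translational partition function matches the de Broglie oracle", {
  # independent oracle: q_trans = (kB T / p) / Lambda^3
  cst <- qge_constants()
  M <- 58.12; T0 <- 200; p <- 1e5
  lambda <- cst$h / sqrt(2 * pi * M * cst$amu * cst$kB * T0)
  ln_q_oracle <- log((cst$kB * T0 / p) / lambda^3)
  ref <- reference_conformation(rbind(c(0, 0, 0), c(0.15, 0, 0),
                                      c(0.2, 0.14, 0)),
                                c(M / 3, M / 3, M / 3))
  lq <- rt_log_partition(ref, T0, p)
  expect_equal(lq$ln_q_trans, ln_q_oracle, tolerance = 1e-10)
  expect_equal(lq$ln_q_trans, 15.69, tolerance = 1e-2)

  # doubling the mass raises ln q_trans by 1.5 ln 2 (inertia fixed)
  ref2 <- ref; ref2$M <- 2 * ref$M
  expect_equal(rt_log_partition(ref2, T0, p)$ln_q_trans,
               lq$ln_q_trans + 1.5 * log(2), tolerance = 1e-10)

  # gamma = 1 halves the rotational partition function
  refg <- ref; refg$gamma <- 1
  expect_equal(rt_log_partition(refg, T0, p)$ln_q_rot,
               lq$ln_q_rot - log(2), tolerance = 1e-12)

  # a linear molecule is unsupported
  lin <- reference_conformation(rbind(c(0, 0, 0), c(0.1, 0, 0)), c(10, 10))
  expect_error(rt_log_partition(lin, T0, p), "linear")
})

test_that("internal partition function has the right limits", {
  expect_equal(in_log_partition(numeric(0), 200, Ue_ref = 0), 0)
  # pure reference energy: -beta0 Ue
  expect_equal(in_log_partition(numeric(0), 200, Ue_ref = 3.2),
               -3.2 / (kB_kJ * 200), tolerance = 1e-12)
  # classical limit: per-mode factor ~ ln(kB T / h nu) within 1 percent
  cst <- qge_constants()
  wn <- 0.5  # very soft mode: beta h nu << 1 at 300 K
  x <- cst$h * wn * 2.99792458e10 / (cst$kB * 300)
  expect_equal(in_log_partition(wn, 300) / log(1 / x), 1, tolerance = 0.01)
  expect_error(in_log_partition(c(10, -1), 200), "positive")
})

test_that("trajectory deltas obey the thermodynamic identity", {
  # P_ref = 1 with equal means: all deltas vanish
  d0 <- md_deltas(1, -5, -5, 200)
  expect_equal(c(d0$dmu0, d0$dh0, d0$ds0), c(0, 0, 0))

  # inverse of the published row: P_ref = 0.0389 -> dmu0 ~ 5.40 kJ/mol
  d <- md_deltas(0.0389, 0, 0, 200)
  expect_equal(d$dmu0, -kB_kJ * 200 * log(0.0389), tolerance = 1e-12)
  expect_equal(d$dmu0, 5.40, tolerance = 1e-2)

  # identity ds0 = (dh0 - dmu0)/T0 holds exactly for random inputs
  set.seed(1)
  for (i in 1:20) {
    dd <- md_deltas(runif(1, 1e-4, 1), runif(1, -30, 30), runif(1, -30, 30),
                    runif(1, 100, 400))
    expect_equal(dd$ds0, (dd$dh0 - dd$dmu0) / dd$T0 * 1000, tolerance = 1e-12)
  }
  expect_error(md_deltas(0, 0, 0, 200), "lengthen the sampling")
  expect_error(md_deltas(1.2, 0, 0, 200), "exceed")
})

test_that("anchor assembly matches an independent transcription of the formulas", {
  set.seed(99)
  cst <- qge_constants()
  for (i in 1:5) {
    coords <- matrix(runif(12, -0.2, 0.2), 4, 3)
    masses <- runif(4, 1, 16)
    nu_cl <- sort(runif(3, 30, 200))
    Ue <- runif(1, -15, 15)
    T0 <- 200; p <- 1e5
    ref <- reference_conformation(coords, masses, Ue_ref = Ue,
                                  nu_cl = nu_cl, gamma = 0)
    Pref <- runif(1, 0.05, 0.95)
    mur <- runif(1, -10, 0); mua <- runif(1, -10, 0)
    deltas <- md_deltas(Pref, mur, mua, T0)
    anc <- excess_anchors(ref, deltas, p = p, cp0p = 60)

    # independent, term-by-term evaluation (molar units)
    kT <- kB_kJ * T0
    hnu <- cst$h * nu_cl * 2.99792458e10 * cst$NA_ / 1000
    x <- hnu / kT
    lq_rt <- rt_log_partition(ref, T0, p)$ln_q_rt
    lq_in <- -Ue / kT + sum(-x / 2 - log1p(-exp(-x)))
    mu0_expect <- -kT * (lq_rt + lq_in) + kT + kT * log(Pref)
    h0_expect <- Ue + sum(hnu) / 2 + sum(hnu * exp(-x) / (1 - exp(-x))) +
      4 * kT - (mur - mua)
    expect_equal(anc$mu0p, mu0_expect, tolerance = 1e-10)
    expect_equal(anc$h0p, h0_expect, tolerance = 1e-10)
    # s0' = (h0' - mu0')/T0 to machine precision
    expect_equal(anc$s0p, (anc$h0p - anc$mu0p) / T0 * 1000,
                 tolerance = 1e-12)
  }
})

test_that("anchors are invariant under rigid motion and monotone in P_ref", {
  set.seed(5)
  coords <- matrix(runif(15, -0.25, 0.25), 5, 3)
  masses <- runif(5, 2, 14)
  nu_cl <- c(55, 90, 140)
  mk_ref <- function(X) reference_conformation(X, masses, Ue_ref = 1.5,
                                               nu_cl = nu_cl)
  deltas <- md_deltas(0.4, -2, -2.5, 200)
  a1 <- excess_anchors(mk_ref(coords), deltas, cp0p = 60)
  R <- random_rotation(11)
  a2 <- excess_anchors(mk_ref(sweep(coords %*% t(R), 2, c(0.3, -1, 2), "+")),
                       deltas, cp0p = 60)
  expect_equal(a1$mu0p, a2$mu0p, tolerance = 1e-9)
  expect_equal(a1$s0p, a2$s0p, tolerance = 1e-8)

  # increasing P_ref (larger box) increases the kB T0 ln(P_ref) term and
  # hence mu0'
  mus <- sapply(c(0.2, 0.4, 0.6, 0.9), function(P)
    excess_anchors(mk_ref(coords), md_deltas(P, -2, -2.5, 200),
                   cp0p = 60)$mu0p)
  expect_true(all(diff(mus) > 0))

  # with zero deltas (P_ref = 1, equal means) the anchors are the pure
  # reference-conformation values
  a0 <- excess_anchors(mk_ref(coords), md_deltas(1, -2, -2, 200), cp0p = 60)
  kT <- kB_kJ * 200
  lq <- rt_log_partition(mk_ref(coords), 200, 1e5)$ln_q_rt +
    in_log_partition(mk_ref(coords), 200)
  expect_equal(a0$mu0p, -kT * lq + kT, tolerance = 1e-10)

  # T0 mismatch is a configuration error
  expect_error(excess_anchors(mk_ref(coords), deltas, T0 = 250, cp0p = 60),
               "mismatch")
})
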