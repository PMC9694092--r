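# Gamma-state equation of state and quantum vibrational terms.

test_that("anchors validate and excess thermo reduces to them at T0", {
  a <- gamma_anchors(T0 = 200, p = 1e5, h0p = 9.9, s0p = 302.1, cp0p = 64.5)
  et <- excess_thermo(a, 200)
  expect_equal(et$mu_p, a$mu0p)
  expect_equal(et$s_p, 302.1)
  expect_equal(et$h_p, 9.9)
  expect_equal(et$cp_p, 64.5)

  # consistent mu0p accepted, inconsistent rejected
  expect_silent(gamma_anchors(T0 = 200, h0p = 9.9, s0p = 302.1, cp0p = 64.5,
                              mu0p = 9.9 - 200 * 302.1 / 1000))
  expect_error(gamma_anchors(T0 = 200, h0p = 9.9, s0p = 302.1, cp0p = 64.5,
                             mu0p = 0), "inconsistent")
  expect_error(gamma_anchors(T0 = -5, h0p = 1, s0p = 1, cp0p = 1), "positive")
  expect_error(excess_thermo(a, 0), "positive")
  expect_warning(excess_thermo(a, 150), "below T0")
})

test_that("excess thermo reproduces the tabulated n-butane values", {
  # anchors relative to the T = 0 reference enthalpy (published table, row 1)
  a <- gamma_anchors(T0 = 200, p = 1e5, h0p = 9.9, s0p = 302.1, cp0p = 64.5)
  et <- excess_thermo(a, 300)
  expect_equal(et$h_p, 9.9 + 64.5 * 100 / 1000, tolerance = 1e-12) # 16.35
  expect_equal(et$s_p, 302.1 + 64.5 * log(1.5), tolerance = 1e-12) # 328.25
})

test_that("vibrational thermodynamics matches closed-form oracles", {
  # empty mode set: all zero
  v0 <- vib_thermo(numeric(0), c(100, 300, 1000))
  expect_true(all(v0$mu_vib == 0 & v0$h_vib == 0 & v0$s_vib == 0 &
                    v0$cp_vib == 0))

  # one mode at 1000 cm^-1, 300 K: Einstein heat capacity, independent form
  cst <- qge_constants()
  x <- cst$h * 1000 * 2.99792458e10 / (cst$kB * 300)
  cp_oracle <- cst$R * x^2 * exp(x) / expm1(x)^2
  v <- vib_thermo(1000, 300)
  expect_equal(v$cp_vib, cp_oracle, tolerance = 1e-10)
  expect_equal(v$cp_vib, 1.6067, tolerance = 1e-3)

  # equipartition limit: cp -> n kB per mode
  wn <- c(200, 800, 1500)
  vhi <- vib_thermo(wn, 1e7)
  expect_equal(vhi$cp_vib, 3 * cst$R, tolerance = 1e-6)

  # T -> 0: cp -> 0, h -> ZPE, s -> 0
  vlo <- vib_thermo(wn, 1)
  zpe <- sum(cst$h * wn * 2.99792458e10 * cst$NA_ / 1000) / 2
  expect_equal(vlo$cp_vib, 0, tolerance = 1e-8)
  expect_equal(vlo$h_vib, zpe, tolerance = 1e-10)
  expect_equal(vlo$s_vib, 0, tolerance = 1e-8)

  # linearity: duplicating the mode list doubles every term
  v1 <- vib_thermo(wn, 400)
  v2 <- vib_thermo(c(wn, wn), 400)
  for (col in c("mu_vib", "h_vib", "s_vib", "cp_vib"))
    expect_equal(v2[[col]], 2 * v1[[col]], tolerance = 1e-12)

  expect_error(vib_thermo(c(100, -5), 300), "positive")
  expect_error(vib_thermo(c(100, 0), 300), "positive")
})

test_that("reference zero-point bookkeeping is correct", {
  rz0 <- reference_zero(Ue_ref = -10)
  expect_equal(rz0$href0, -10)
  expect_equal(rz0$hrefp0, -10)
  expect_equal(rz0$sref0, 0)

  cst <- qge_constants()
  half <- function(wn) cst$h * wn * 2.99792458e10 * cst$NA_ / 1000 / 2
  rz <- reference_zero(quantum = 2000, Ue_ref = 0, cl_modes = 100)
  expect_equal(rz$hrefp0, half(100), tolerance = 1e-12)
  expect_equal(rz$href0, half(100) + half(2000), tolerance = 1e-12)
  expect_equal(rz$sref0, 0)
})

test_that("full thermodynamics satisfies the consistency identities", {
  set.seed(42)
  for (rep in 1:5) {
    a <- gamma_anchors(T0 = runif(1, 150, 300), p = 1e5,
                       h0p = runif(1, -50, 50), s0p = runif(1, 100, 700),
                       cp0p = runif(1, 20, 300))
    wn <- sort(runif(sample(0:12, 1), 80, 3000))
    rz <- reference_zero(quantum = wn, Ue_ref = runif(1, -20, 20))
    Tg <- seq(a$T0, a$T0 + 400, length.out = 21)
    tab <- full_thermo(a, wn, rz, Tg)

    # h = mu + T s at every grid point (kJ/mol vs J/(mol K))
    expect_equal(tab$h_minus_href0,
                 tab$mu_minus_href0 + Tg * tab$s / 1000, tolerance = 1e-9)
    # excess identity as well
    expect_equal(tab$hp_minus_hrefp0,
                 tab$mup_minus_hrefp0 + Tg * tab$sp / 1000, tolerance = 1e-9)
    # quantum terms only add to the heat capacity
    expect_true(all(tab$cp >= a$cp0p - 1e-9))
    # full cp minus the vibrational part is the constant cp0'
    vt <- vib_thermo(wn, Tg)
    expect_equal(tab$cp - vt$cp_vib, rep(a$cp0p, 21), tolerance = 1e-9)

    # s = -d mu / dT by central differences, relative error < 1e-6
    h <- 1e-3
    Tm <- Tg[3:19]
    mu_p <- full_thermo(a, wn, rz, Tm + h)$mu_minus_href0
    mu_m <- full_thermo(a, wn, rz, Tm - h)$mu_minus_href0
    s_fd <- -(mu_p - mu_m) / (2 * h) * 1000
    s_an <- full_thermo(a, wn, rz, Tm)$s
    expect_lt(max(abs(s_fd - s_an) / abs(s_an)), 1e-6)
  }
})

test_that("degenerate inputs: no modes and zero cp0' give constant entropy", {
  a <- gamma_anchors(T0 = 250, h0p = 5, s0p = 180, cp0p = 0)
  tab <- full_thermo(a, numeric(0), reference_zero(), seq(250, 500, 50))
  expect_true(all(abs(tab$s - 180) < 1e-12))
  # enthalpy exactly linear (here constant, cp0' = 0)
  expect_true(all(abs(diff(tab$h_minus_href0)) < 1e-12))
  expect_error(full_thermo(a, numeric(0), list(), 300), "reference_zero")
})

test_that("gamma_eos model object round-trips through its methods", {
  a <- gamma_anchors(T0 = 200, h0p = 9.9, s0p = 302.1, cp0p = 64.5)
  eos <- gamma_eos(a, quantum_modes(c(300, 900, 1400), "synthetic"))
  cf <- coef(eos)
  expect_equal(unname(cf["h0p"]), 9.9)
  expect_equal(unname(cf["mu0p"]), 9.9 - 200 * 302.1 / 1000)
  tab <- predict(eos, T = c(200, 300, 400))
  expect_s3_class(tab, "thermo_table")
  expect_equal(nrow(tab), 3)
  expect_output(print(eos), "Gamma-state")
  expect_output(print(summary(eos)), "isobar")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(eos, T = seq(200, 400, 50)))
})
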