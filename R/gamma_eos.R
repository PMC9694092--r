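# Diverging-Gamma-state isobaric equation of state plus quantum
# harmonic-oscillator vibrational contributions.
#
# The excess (semi-classical/configurational) thermodynamics along an isobar
# is fixed by four anchors at a reference temperature T0: the excess enthalpy
# h0', entropy s0' and heat capacity cp0' (constant along the isobar), from
# which
#   mu'(T) = h0' - T0 cp0' + T (cp0' - s0') + T cp0' ln(T0/T)
#   s'(T)  = s0' + cp0' ln(T/T0)
#   h'(T)  = h0' + cp0' (T - T0)
#   cp'(T) = cp0'
# The quantum modes (high-frequency stretches/bends) add the usual harmonic
# oscillator terms, giving the complete molecular thermodynamics.

#' Gamma-state anchors at the reference temperature
#'
#' Bundles the excess thermodynamic state at `(T0, p)` that fixes the
#' diverging-Gamma-state isobar: excess enthalpy, entropy and (constant)
#' isobaric heat capacity.  The excess chemical potential is derived as
#' `h0p - T0 * s0p / 1000` unless supplied, in which case it is checked for
#' consistency.
#'
#' @param T0 Reference temperature (K), positive.
#' @param p Pressure (Pa), positive.  Default 1 bar.
#' @param h0p Excess enthalpy at `T0` (kJ/mol).  May be expressed relative to
#'   any fixed zero (e.g. the reference-conformation enthalpy at T = 0); the
#'   same zero then applies to all enthalpies/chemical potentials derived
#'   from these anchors.
#' @param s0p Excess entropy at `T0` (J/(mol K)).
#' @param cp0p Excess isobaric heat capacity (J/(mol K)), constant in the
#'   Gamma state.
#' @param mu0p Optional excess chemical potential at `T0` (kJ/mol); checked
#'   against `h0p - T0 * s0p / 1000` within `tol`.
#' @param tol Absolute tolerance (kJ/mol) for the `mu0p` consistency check.
#' @return Object of class `"gamma_anchors"`.
#' @export
gamma_anchors <- function(T0, p = 1e5, h0p, s0p, cp0p, mu0p = NULL,
                          tol = 1e-6) {
  stopifnot(is.numeric(T0), length(T0) == 1L, is.finite(T0),
            is.numeric(p), length(p) == 1L, is.finite(p))
  if (T0 <= 0) stop("T0 must be positive")
  if (p <= 0) stop("p must be positive")
  h0p <- as.numeric(h0p); s0p <- as.numeric(s0p); cp0p <- as.numeric(cp0p)
  stopifnot(length(h0p) == 1L, length(s0p) == 1L, length(cp0p) == 1L,
            is.finite(h0p), is.finite(s0p), is.finite(cp0p))
  mu_derived <- h0p - T0 * s0p / 1000
  if (!is.null(mu0p)) {
    if (abs(mu0p - mu_derived) > tol)
      stop(sprintf("mu0p (%.6g) inconsistent with h0p - T0*s0p (%.6g)",
                   mu0p, mu_derived))
  } else {
    mu0p <- mu_derived
  }
  structure(list(T0 = T0, p = p, h0p = h0p, s0p = s0p, cp0p = cp0p,
                 mu0p = mu0p),
            class = "gamma_anchors")
}

#' @export
print.gamma_anchors <- function(x, ...) {
  cat("Gamma-state anchors\n")
  cat(sprintf("  T0   = %g K,  p = %g Pa\n", x$T0, x$p))
  cat(sprintf("  h0'  = %.4g kJ/mol\n", x$h0p))
  cat(sprintf("  s0'  = %.4g J/(mol K)\n", x$s0p))
  cat(sprintf("  cp0' = %.4g J/(mol K)\n", x$cp0p))
  cat(sprintf("  mu0' = %.4g kJ/mol\n", x$mu0p))
  invisible(x)
}

#' Quantum-mode frequency set
#'
#' A validated vector of harmonic mode wavenumbers treated as
#' temperature-independent quantum oscillators.
#'
#' @param wavenumbers Numeric vector of mode wavenumbers (cm^-1), all
#'   positive.  May be empty (a rigid or mode-free system).
#' @param provenance Character tag recording where the frequencies came from
#'   (`"force-field"`, `"quantum-chemistry"` or `"synthetic"`).
#' @return Object of class `"quantum_modes"`.
#' @export
quantum_modes <- function(wavenumbers = numeric(0),
                          provenance = c("force-field", "quantum-chemistry",
                                         "synthetic")) {
  provenance <- match.arg(provenance)
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) && (any(!is.finite(wavenumbers)) ||
                              any(wavenumbers <= 0)))
    stop("all mode wavenumbers must be finite and positive")
  structure(list(wavenumbers = wavenumbers, provenance = provenance),
            class = "quantum_modes")
}

#' @export
print.quantum_modes <- function(x, ...) {
  cat(sprintf("quantum_modes: %d modes (%s)\n",
              length(x$wavenumbers), x$provenance))
  if (length(x$wavenumbers))
    cat(sprintf("  range %.4g - %.4g cm^-1\n",
                min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

as_wavenumbers <- function(modes) {
  if (inherits(modes, "quantum_modes")) modes$wavenumbers
  else as.numeric(modes)
}

#' Excess (Gamma-state) thermodynamics along the isobar
#'
#' Evaluates the diverging-Gamma-state excess chemical potential, entropy,
#' enthalpy and heat capacity at temperatures `T`, from anchors at `T0`.
#' The model is physically meaningful for `T >= T0` (below `T0` the internal
#' coordinates are no longer semi-classical); evaluation at `T < T0` warns
#' but proceeds.
#'
#' @param anchors A [gamma_anchors()] object.
#' @param T Temperature vector (K), positive.
#' @return `data.frame` with columns `T`, `mu_p` (kJ/mol), `s_p`
#'   (J/(mol K)), `h_p` (kJ/mol), `cp_p` (J/(mol K)).
#' @export
excess_thermo <- function(anchors, T) {
  stopifnot(inherits(anchors, "gamma_anchors"))
  T <- as.numeric(T)
  if (!length(T) || any(!is.finite(T)) || any(T <= 0))
    stop("temperatures must be finite and positive")
  if (any(T < anchors$T0))
    warning("Gamma state evaluated below T0; the model is not valid there")
  T0 <- anchors$T0
  cp <- anchors$cp0p   # J/(mol K)
  s0 <- anchors$s0p    # J/(mol K)
  h0 <- anchors$h0p    # kJ/mol
  mu_p <- h0 - T0 * cp / 1000 + T * (cp - s0) / 1000 + T * cp * log(T0 / T) / 1000
  s_p <- s0 + cp * log(T / T0)
  h_p <- h0 + cp * (T - T0) / 1000
  data.frame(T = T, mu_p = mu_p, s_p = s_p, h_p = h_p,
             cp_p = rep(cp, length(T)))
}

#' Quantum harmonic-oscillator vibrational thermodynamics
#'
#' Standard temperature-independent-frequency harmonic oscillator sums: the
#' vibrational chemical potential and enthalpy include the zero-point energy;
#' the entropy follows from `(h - mu)/T` and the heat capacity is the Einstein
#' form per mode.
#'
#' @param modes A [quantum_modes()] object or numeric wavenumber vector
#'   (cm^-1).
#' @param T Temperature vector (K), positive.
#' @return `data.frame` with columns `T`, `mu_vib`, `h_vib` (kJ/mol),
#'   `s_vib`, `cp_vib` (J/(mol K)).
#' @export
vib_thermo <- function(modes, T) {
  wn <- as_wavenumbers(modes)
  if (length(wn) && (any(!is.finite(wn)) || any(wn <= 0)))
    stop("all mode wavenumbers must be finite and positive")
  T <- as.numeric(T)
  if (!length(T) || any(!is.finite(T)) || any(T <= 0))
    stop("temperatures must be finite and positive")
  n <- length(T)
  if (!length(wn)) {
    return(data.frame(T = T, mu_vib = numeric(n), h_vib = numeric(n),
                      s_vib = numeric(n), cp_vib = numeric(n)))
  }
  zpe <- sum(hnu_molar(wn)) / 2          # kJ/mol
  hnu <- hnu_molar(wn)                   # kJ/mol per mode
  mu <- h <- s <- cp <- numeric(n)
  for (i in seq_len(n)) {
    x <- hnu_over_kT(wn, T[i])
    emx <- exp(-x)
    mu[i] <- zpe + .kB_kJ * T[i] * sum(log1p(-emx))
    h[i] <- zpe + sum(hnu * emx / (1 - emx))
    s[i] <- (h[i] - mu[i]) / T[i] * 1000
    # x^2 e^-x / (1-e^-x)^2 is the overflow-safe Einstein form
    cp[i] <- .R_J * sum(x^2 * emx / (1 - emx)^2)
  }
  data.frame(T = T, mu_vib = mu, h_vib = h, s_vib = s, cp_vib = cp)
}

#' Reference-conformation zero-temperature energies
#'
#' The zeros against which the full thermodynamics is reported: the excess
#' reference enthalpy at T = 0 is the electronic/force-field minimum energy
#' plus the semi-classical zero-point energy; the full reference enthalpy
#' adds the quantum-mode zero-point energy; the reference entropy at T = 0
#' is zero by convention.
#'
#' @param quantum Quantum-mode wavenumbers (cm^-1) or [quantum_modes()].
#' @param Ue_ref Electronic (or force-field) reference energy at the minimum
#'   (kJ/mol).
#' @param cl_modes Semi-classical mode wavenumbers (cm^-1) or
#'   [quantum_modes()].
#' @return Object of class `"reference_zero"` with fields `hrefp0`, `href0`
#'   (kJ/mol) and `sref0 = 0`.
#' @export
reference_zero <- function(quantum = numeric(0), Ue_ref = 0,
                           cl_modes = numeric(0)) {
  nu_q <- as_wavenumbers(quantum)
  nu_cl <- as_wavenumbers(cl_modes)
  stopifnot(is.numeric(Ue_ref), length(Ue_ref) == 1L, is.finite(Ue_ref))
  hrefp0 <- Ue_ref + sum(hnu_molar(nu_cl)) / 2
  href0 <- hrefp0 + sum(hnu_molar(nu_q)) / 2
  structure(list(hrefp0 = hrefp0, href0 = href0, sref0 = 0),
            class = "reference_zero")
}

#' @export
print.reference_zero <- function(x, ...) {
  cat(sprintf("reference zero: h'_ref(0) = %.6g kJ/mol, h_ref(0) = %.6g kJ/mol, s_ref(0) = 0\n",
              x$hrefp0, x$href0))
  invisible(x)
}

#' Complete molecular thermodynamics along the isobar
#'
#' Combines the Gamma-state excess part with the quantum-mode harmonic
#' contributions, reporting enthalpy and chemical potential relative to the
#' reference-conformation enthalpy at T = 0 (`href0`), with the entropy
#' absolute (`s_ref(0) = 0`).
#'
#' @param anchors [gamma_anchors()] at `(T0, p)`.  `anchors$h0p` must be on
#'   the same energy zero as `refzero$hrefp0` (both absolute, or both already
#'   relative with `refzero` zeros at 0).
#' @param modes Quantum modes ([quantum_modes()] or wavenumber vector).
#' @param refzero A [reference_zero()] object.
#' @param Tgrid Temperature grid (K), each `>= anchors$T0` (warned
#'   otherwise).
#' @return A `"thermo_table"` `data.frame` with columns `T`,
#'   `mu_minus_href0`, `h_minus_href0` (kJ/mol), `s`, `cp` (J/(mol K)) and
#'   the excess-only columns `mup_minus_hrefp0`, `hp_minus_hrefp0` (kJ/mol),
#'   `sp`, `cpp` (J/(mol K)).
#' @export
full_thermo <- function(anchors, modes, refzero, Tgrid) {
  if (missing(anchors) || !inherits(anchors, "gamma_anchors"))
    stop("configuration error: 'anchors' must be a gamma_anchors object")
  if (missing(modes)) stop("configuration error: 'modes' is required")
  if (!inherits(refzero, "reference_zero"))
    stop("configuration error: 'refzero' must be a reference_zero object")
  ex <- excess_thermo(anchors, Tgrid)
  vb <- vib_thermo(modes, Tgrid)
  wn <- as_wavenumbers(modes)
  zpe_q <- sum(hnu_molar(wn)) / 2
  hp_rel <- ex$h_p - refzero$hrefp0
  mup_rel <- ex$mu_p - refzero$hrefp0
  h_rel <- hp_rel + (vb$h_vib - zpe_q)
  mu_rel <- mup_rel + (vb$mu_vib - zpe_q)
  s <- ex$s_p + vb$s_vib
  cp <- ex$cp_p + vb$cp_vib
  out <- data.frame(T = ex$T,
                    mu_minus_href0 = mu_rel,
                    h_minus_href0 = h_rel,
                    s = s, cp = cp,
                    mup_minus_hrefp0 = mup_rel,
                    hp_minus_hrefp0 = hp_rel,
                    sp = ex$s_p, cpp = ex$cp_p)
  class(out) <- c("thermo_table", "data.frame")
  out
}

#' Gamma-state equation-of-state model object
#'
#' Constructs the analytic isobaric equation of state from its anchors,
#' quantum modes and reference zeros.  `predict()` evaluates the complete
#' thermodynamics on a temperature grid, `coef()` returns the anchor
#' parameters and `plot()` draws enthalpy, entropy and heat capacity versus
#' temperature.
#'
#' @param anchors [gamma_anchors()].
#' @param modes [quantum_modes()] or wavenumber vector (cm^-1); may be
#'   empty.
#' @param refzero [reference_zero()]; defaults to zeros (anchors then
#'   interpreted as already relative to the T = 0 reference enthalpy).
#' @return Object of class `"gamma_eos"`.
#' @export
gamma_eos <- function(anchors, modes = quantum_modes(),
                      refzero = NULL) {
  stopifnot(inherits(anchors, "gamma_anchors"))
  if (!inherits(modes, "quantum_modes")) modes <- quantum_modes(modes)
  if (is.null(refzero)) refzero <- reference_zero()
  stopifnot(inherits(refzero, "reference_zero"))
  structure(list(anchors = anchors, modes = modes, refzero = refzero),
            class = "gamma_eos")
}

#' @export
print.gamma_eos <- function(x, ...) {
  cat("Gamma-state isobaric equation of state\n")
  print(x$anchors)
  cat(sprintf("  %d quantum modes (%s); h_ref(0) = %.6g kJ/mol\n",
              length(x$modes$wavenumbers), x$modes$provenance,
              x$refzero$href0))
  invisible(x)
}

#' @export
coef.gamma_eos <- function(object, ...) {
  a <- object$anchors
  c(T0 = a$T0, p = a$p, h0p = a$h0p, s0p = a$s0p, cp0p = a$cp0p,
    mu0p = a$mu0p)
}

#' Predict thermodynamic properties from a Gamma-state model
#'
#' @param object A [gamma_eos()] model.
#' @param T Temperature grid (K); defaults to `T0 ... T0 + 400` in 10 K
#'   steps.
#' @param ... Unused.
#' @return A `"thermo_table"` data.frame (see [full_thermo()]).
#' @export
predict.gamma_eos <- function(object, T = NULL, ...) {
  if (is.null(T))
    T <- seq(object$anchors$T0, object$anchors$T0 + 400, by = 10)
  full_thermo(object$anchors, object$modes, object$refzero, T)
}

#' @export
summary.gamma_eos <- function(object, ...) {
  tab <- predict(object)
  res <- list(model = object, table = tab)
  class(res) <- "summary.gamma_eos"
  res
}

#' @export
print.summary.gamma_eos <- function(x, ...) {
  print(x$model)
  idx <- unique(round(seq(1, nrow(x$table), length.out = 6)))
  cat("\nThermodynamics on the isobar (relative to h_ref(0)):\n")
  print(format(x$table[idx, c("T", "h_minus_href0", "s", "cp")],
               digits = 5), row.names = FALSE)
  invisible(x)
}

#' @export
plot.gamma_eos <- function(x, T = NULL, ...) {
  tab <- predict(x, T = T)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tab$T, tab$h_minus_href0, type = "l", xlab = "T (K)",
                 ylab = "h - h_ref(0) (kJ/mol)", main = "Enthalpy", ...)
  graphics::plot(tab$T, tab$s, type = "l", xlab = "T (K)",
                 ylab = "s (J/(mol K))", main = "Entropy", ...)
  graphics::plot(tab$T, tab$cp, type = "l", xlab = "T (K)",
                 ylab = "cp (J/(mol K))", main = "Heat capacity", ...)
  invisible(tab)
}
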