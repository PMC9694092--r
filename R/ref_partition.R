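# Reference-conformation partition functions and the excess anchors at T0.
#
# The reference conformation is a harmonic basin around a minimum-energy
# structure.  Its ideal-gas partition function factorizes into a
# roto-translational part (rigid rotor + translation at pressure p) and an
# internal part (electronic minimum energy times quantum harmonic oscillators
# on the semi-classical modes).  Combining these with the trajectory-derived
# basin probability P_ref and potential-energy means yields the Gamma-state
# anchors at T0:
#   mu0' = -kB T0 ln(q_rt q_in) + kB T0 + kB T0 ln(P_ref)
#   h0'  = Ue_ref + sum h nu_cl/2 + sum h nu_cl e^-x/(1-e^-x) + 4 kB T0
#          - (<U_pot>_ref,0 - <U_pot>_0)
#   s0'  = (h0' - mu0') / T0

#' Reference-conformation description
#'
#' Minimum-energy structure with everything the reference partition
#' functions need: masses, electronic/force-field minimum energy, principal
#' inertia moments (computed from the coordinates), the nuclear-permutation
#' correction gamma, and the semi-classical and quantum mode wavenumbers.
#' Inertia moments and frequencies may come from different sources (e.g.
#' force field vs quantum chemistry); record that in the mode provenance.
#'
#' @param coords Minimum-energy coordinates, `n x 3` matrix (nm).
#' @param masses Atomic masses (amu), length `n`.
#' @param Ue_ref Electronic/force-field energy at the minimum (kJ/mol).
#' @param nu_cl Semi-classical mode wavenumbers (cm^-1), length `n_in`.
#' @param nu_q Quantum mode wavenumbers (cm^-1).
#' @param gamma Quantum correction for nuclear permutations under rotation;
#'   the rotational partition function carries a factor `1/(1 + gamma)`.
#'   Default 0 (symmetry number 1).
#' @return Object of class `"reference_conformation"` with fields `coords`,
#'   `masses`, `M` (total mass, amu), `Ue_ref`, `inertia` (ascending
#'   principal moments, amu nm^2), `gamma`, `nu_cl`, `nu_q`.
#' @export
reference_conformation <- function(coords, masses, Ue_ref = 0,
                                   nu_cl = numeric(0), nu_q = numeric(0),
                                   gamma = 0) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L,
            length(masses) == nrow(coords), all(masses > 0),
            is.finite(Ue_ref), gamma >= 0)
  nu_cl <- as_wavenumbers(nu_cl)
  nu_q <- as_wavenumbers(nu_q)
  if (length(nu_cl) && any(nu_cl <= 0)) stop("nu_cl must be positive")
  if (length(nu_q) && any(nu_q <= 0)) stop("nu_q must be positive")
  structure(list(coords = coords, masses = as.numeric(masses),
                 M = sum(masses), Ue_ref = Ue_ref,
                 inertia = principal_inertia(coords, masses),
                 gamma = gamma, nu_cl = nu_cl, nu_q = nu_q),
            class = "reference_conformation")
}

#' @export
print.reference_conformation <- function(x, ...) {
  cat(sprintf("reference conformation: %d atoms, M = %.4g amu\n",
              nrow(x$coords), x$M))
  cat(sprintf("  Ue_ref = %.6g kJ/mol, gamma = %g\n", x$Ue_ref, x$gamma))
  cat(sprintf("  inertia (amu nm^2): %s\n",
              paste(signif(x$inertia, 5), collapse = ", ")))
  cat(sprintf("  %d semi-classical + %d quantum modes\n",
              length(x$nu_cl), length(x$nu_q)))
  invisible(x)
}

#' Principal moments of inertia
#'
#' Eigenvalues of the inertia tensor about the center of mass, ascending.
#'
#' @param coords `n x 3` coordinate matrix (nm).
#' @param masses Masses (amu), length `n`.
#' @return Numeric length-3 vector (amu nm^2), ascending.
#' @export
principal_inertia <- function(coords, masses) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("at least one atom required")
  stopifnot(ncol(coords) == 3L, length(masses) == nrow(coords))
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2, com)
  I <- matrix(0, 3, 3)
  r2 <- rowSums(r^2)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(masses * ((a == b) * r2 - r[, a] * r[, b]))
  }
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Roto-translational log partition function of the reference conformation
#'
#' Translational (ideal gas at pressure `p`) plus rigid-rotor rotational
#' contributions at the minimum-energy structure:
#' `ln q_rt = ln[(2 pi M kB T0 / h^2)^{3/2} kB T0 / p]
#'          + ln[(8 pi^2/(1+gamma)) sqrt(I1 I2 I3) (2 pi kB T0 / h^2)^{3/2}]`.
#' No additional factor of e is included here; the `+ kB T0` term is applied
#' explicitly when assembling the excess chemical potential in
#' [excess_anchors()].
#'
#' @param ref A [reference_conformation()] (or list with fields `M`,
#'   `inertia`, `gamma`).
#' @param T0 Temperature (K), positive.
#' @param p Pressure (Pa), positive.
#' @return List with `ln_q_rt`, `ln_q_trans`, `ln_q_rot` (dimensionless).
#' @export
rt_log_partition <- function(ref, T0, p = 1e5) {
  stopifnot(T0 > 0, p > 0)
  M_kg <- ref$M * .amu
  I_SI <- ref$inertia * .amu * 1e-18          # amu nm^2 -> kg m^2
  if (prod(I_SI) <= 0 || min(I_SI) / max(I_SI) < 1e-12)
    stop("unsupported geometry: linear molecule (a principal moment is zero)")
  ln_trans <- 1.5 * log(2 * pi * M_kg * .kB_SI * T0 / .h_SI^2) +
    log(.kB_SI * T0 / p)
  ln_rot <- log(8 * pi^2 / (1 + ref$gamma)) + 0.5 * sum(log(I_SI)) +
    1.5 * log(2 * pi * .kB_SI * T0 / .h_SI^2)
  list(ln_q_rt = ln_trans + ln_rot, ln_q_trans = ln_trans, ln_q_rot = ln_rot)
}

#' Internal log partition function of the reference conformation
#'
#' Electronic minimum energy plus quantum harmonic oscillators on the
#' semi-classical modes:
#' `ln q_in = -beta0 Ue_ref + sum_j [-beta0 h nu_j,cl / 2 -
#' ln(1 - e^{-beta0 h nu_j,cl})]`.
#'
#' @param ref A [reference_conformation()] (fields `Ue_ref`, `nu_cl` used),
#'   or a numeric vector of semi-classical wavenumbers (then `Ue_ref = 0`).
#' @param T0 Temperature (K), positive.
#' @param Ue_ref Optional override of the reference energy (kJ/mol).
#' @return `ln q_in` (dimensionless, molar energies).
#' @export
in_log_partition <- function(ref, T0, Ue_ref = NULL) {
  stopifnot(T0 > 0)
  if (inherits(ref, "reference_conformation")) {
    nu_cl <- ref$nu_cl
    if (is.null(Ue_ref)) Ue_ref <- ref$Ue_ref
  } else {
    nu_cl <- as_wavenumbers(ref)
    if (is.null(Ue_ref)) Ue_ref <- 0
  }
  if (length(nu_cl) && any(nu_cl <= 0))
    stop("semi-classical wavenumbers must be positive")
  x <- hnu_over_kT(nu_cl, T0)
  -Ue_ref / (.kB_kJ * T0) + sum(-x / 2 - log1p(-exp(-x)))
}

#' Trajectory-derived excess differences at T0
#'
#' Converts the reference-conformation probability and the in-basin /
#' whole-space potential-energy means from the T0 trajectory into the excess
#' free energy, enthalpy and entropy differences between the reference
#' conformation and the full conformational space:
#' `dmu0 = -kB T0 ln(P_ref)`, `dh0 = <U_pot>_ref,0 - <U_pot>_0`,
#' `ds0 = (dh0 - dmu0) / T0`.
#'
#' @param Pref Reference-conformation probability, in (0, 1].
#' @param mean_U_ref Mean potential energy over in-basin frames (kJ/mol).
#' @param mean_U_all Mean potential energy over all frames (kJ/mol).
#' @param T0 Trajectory temperature (K).
#' @return Object of class `"delta_anchors"` with `Pref`, `dmu0`, `dh0`
#'   (kJ/mol), `ds0` (J/(mol K)), `T0`, `mean_U_ref`, `mean_U_all`.
#' @export
md_deltas <- function(Pref, mean_U_ref, mean_U_all, T0) {
  stopifnot(T0 > 0, is.finite(mean_U_ref), is.finite(mean_U_all))
  if (!is.finite(Pref) || Pref <= 0)
    stop("P_ref is zero: no frames inside the reference box; ",
         "lengthen the sampling or reduce k")
  if (Pref > 1) stop("P_ref must not exceed 1")
  dmu0 <- -.kB_kJ * T0 * log(Pref)
  dh0 <- mean_U_ref - mean_U_all
  ds0 <- (dh0 - dmu0) / T0 * 1000
  structure(list(Pref = Pref, dmu0 = dmu0, dh0 = dh0, ds0 = ds0, T0 = T0,
                 mean_U_ref = mean_U_ref, mean_U_all = mean_U_all),
            class = "delta_anchors")
}

#' @export
print.delta_anchors <- function(x, ...) {
  cat(sprintf("excess differences at T0 = %g K (P_ref = %.4g):\n", x$T0, x$Pref))
  cat(sprintf("  dmu0' = %.4g kJ/mol, dh0' = %.4g kJ/mol, ds0' = %.4g J/(mol K)\n",
              x$dmu0, x$dh0, x$ds0))
  invisible(x)
}

#' Gamma-state anchors from reference partition functions and deltas
#'
#' Assembles the excess chemical potential, enthalpy and entropy at T0 from
#' the reference-conformation partition functions and the trajectory-derived
#' differences:
#' `mu0' = -kB T0 ln(q_rt q_in) + kB T0 + kB T0 ln(P_ref)` and
#' `h0' = Ue_ref + ZPE_cl + thermal_cl + 4 kB T0 - dh0`, with
#' `s0' = (h0' - mu0') / T0` exactly.  The `4 kB T0` enthalpy term
#' (translational + rotational kinetic + pV) and the implied `+3 kB` entropy
#' bookkeeping are fixed constants of the rigid-rotor treatment.
#'
#' @param ref A [reference_conformation()].
#' @param deltas A [md_deltas()] object at the same `T0`.
#' @param T0 Reference temperature (K); must match `deltas$T0`.
#' @param p Pressure (Pa).
#' @param cp0p Excess heat capacity (J/(mol K)) to store in the anchors,
#'   typically from [fit_semiclassical()].  `NA` allowed if only the T0
#'   anchors are wanted.
#' @return A [gamma_anchors()] object (with `cp0p` possibly `NA`).
#' @export
excess_anchors <- function(ref, deltas, T0 = deltas$T0, p = 1e5, cp0p = NA) {
  stopifnot(inherits(ref, "reference_conformation"),
            inherits(deltas, "delta_anchors"))
  if (!isTRUE(all.equal(T0, deltas$T0)))
    stop("configuration error: T0 mismatch between reference data (", T0,
         ") and deltas (", deltas$T0, ")")
  lrt <- rt_log_partition(ref, T0, p)$ln_q_rt
  lin <- in_log_partition(ref, T0)
  kT <- .kB_kJ * T0
  mu0p <- -kT * (lrt + lin) + kT + kT * log(deltas$Pref)
  x <- hnu_over_kT(ref$nu_cl, T0)
  hnu <- hnu_molar(ref$nu_cl)
  thermal_cl <- if (length(x)) sum(hnu * exp(-x) / (1 - exp(-x))) else 0
  h0p <- ref$Ue_ref + sum(hnu) / 2 + thermal_cl + 4 * kT - deltas$dh0
  s0p <- (h0p - mu0p) / T0 * 1000
  if (is.na(cp0p)) {
    a <- gamma_anchors(T0 = T0, p = p, h0p = h0p, s0p = s0p, cp0p = 0,
                       mu0p = mu0p)
    a$cp0p <- NA_real_
    a
  } else {
    gamma_anchors(T0 = T0, p = p, h0p = h0p, s0p = s0p, cp0p = cp0p,
                  mu0p = mu0p)
  }
}
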