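# Temperature-series fits: validate the Gamma state (linear excess enthalpy)
# and extract the bending count n_b and the excess heat capacity cp0'.
#
# <U_pot,bending>(T) ~ U(0) + (n_b/2) kB T + U''(0) T^2 / 2   (quadratic fit)
# <U_pot> - <U_pot,bending>(T) ~ a + b T                      (linear fit)
# cp0' = b + (n_in/2 + 4) kB  (semi-classical kinetic + translational and
# rotational kinetic + pV bookkeeping), with b the potential-energy slope.

#' Temperature series of mean potential energies
#'
#' @param T Temperatures (K), at least 3, strictly increasing.
#' @param mean_U_pot Mean total potential energy per temperature (kJ/mol).
#' @param mean_U_bend Mean bending potential energy per temperature (kJ/mol).
#' @param se_U_pot,se_U_bend Optional standard errors (kJ/mol); fits are
#'   weighted by `1/se^2` when provided.
#' @return Object of class `"temperature_series"` (a data.frame).
#' @export
temperature_series <- function(T, mean_U_pot, mean_U_bend,
                               se_U_pot = NULL, se_U_bend = NULL) {
  stopifnot(length(T) >= 3, all(diff(T) > 0),
            length(mean_U_pot) == length(T),
            length(mean_U_bend) == length(T))
  d <- data.frame(T = T, mean_U_pot = mean_U_pot, mean_U_bend = mean_U_bend)
  d$se_U_pot <- if (is.null(se_U_pot)) NA_real_ else se_U_pot
  d$se_U_bend <- if (is.null(se_U_bend)) NA_real_ else se_U_bend
  class(d) <- c("temperature_series", "data.frame")
  d
}

fit_weights <- function(se) {
  if (all(is.na(se))) NULL else 1 / se^2
}

#' Quadratic fit of the mean bending energy
#'
#' Fits `<U_pot,bending>` against `U(0) + (n_b/2) kB T + U''(0) T^2 / 2`
#' (weighted least squares when standard errors are available) and reports
#' the bending degree-of-freedom count `n_b` implied by the linear
#' (equipartition) term.
#'
#' @param series A [temperature_series()].
#' @return List of class `"bending_fit"`: `intercept` (kJ/mol), `nb`,
#'   `nb_int`, `quad` (the `U''(0)` coefficient, kJ/mol/K^2), `r2`, `fit`
#'   (the `lm`).
#' @export
fit_bending <- function(series) {
  stopifnot(inherits(series, "temperature_series"), nrow(series) >= 3)
  w <- fit_weights(series$se_U_bend)
  fit <- stats::lm(mean_U_bend ~ T + I(T^2), data = series, weights = w)
  if (any(!is.finite(coef(fit)))) stop("singular design in bending fit")
  b <- coef(fit)
  sm <- suppressWarnings(summary(fit))   # exact data trips a perfect-fit note
  structure(list(intercept = unname(b[1]),
                 nb = unname(2 * b[2] / .kB_kJ),
                 nb_int = as.integer(round(2 * b[2] / .kB_kJ)),
                 quad = unname(2 * b[3]),
                 r2 = sm$r.squared, fit = fit),
            class = "bending_fit")
}

#' @export
print.bending_fit <- function(x, ...) {
  cat(sprintf("bending fit: n_b = %.3f (nearest integer %d), U(0) = %.4g kJ/mol, U''(0) = %.3g, R^2 = %.5f\n",
              x$nb, x$nb_int, x$intercept, x$quad, x$r2))
  invisible(x)
}

#' Linear fit of the semi-classical potential energy and cp0' assembly
#'
#' Fits `<U_pot> - <U_pot,bending>` linearly in temperature and assembles the
#' excess isobaric heat capacity as
#' `cp0' = slope + (n_in/2) kB + 4 kB` (molar): the potential-energy slope of
#' the semi-classical degrees of freedom plus their kinetic equipartition
#' term plus the translational + rotational kinetic and pV terms.  The
#' `(n_in/2 + 4) kB` constant can be overridden via `kinetic_kB`.
#'
#' @param series A [temperature_series()].
#' @param n_in Number of semi-classical internal modes.
#' @param kinetic_kB Multiplier of `kB` added to the slope
#'   (default `n_in/2 + 4`).
#' @return List of class `"semiclassical_fit"`: `intercept` (kJ/mol),
#'   `slope` (kJ/mol/K), `cp0p` (J/(mol K)), `r2`, `fit`.
#' @export
fit_semiclassical <- function(series, n_in, kinetic_kB = n_in / 2 + 4) {
  stopifnot(inherits(series, "temperature_series"), nrow(series) >= 3,
            n_in >= 0)
  series$y <- series$mean_U_pot - series$mean_U_bend
  w <- fit_weights(series$se_U_pot)
  fit <- stats::lm(y ~ T, data = series, weights = w)
  if (any(!is.finite(coef(fit)))) stop("singular design in semi-classical fit")
  b <- coef(fit)
  slope <- unname(b[2])                     # kJ/mol/K
  cp0p <- slope * 1000 + kinetic_kB * .R_J  # J/(mol K)
  sm <- suppressWarnings(summary(fit))
  structure(list(intercept = unname(b[1]), slope = slope, cp0p = cp0p,
                 n_in = n_in, kinetic_kB = kinetic_kB,
                 slope_se = sm$coefficients[2, 2],
                 r2 = sm$r.squared, fit = fit),
            class = "semiclassical_fit")
}

#' @export
print.semiclassical_fit <- function(x, ...) {
  cat(sprintf("semi-classical fit: slope = %.4g kJ/mol/K (se %.2g), cp0' = %.4g J/(mol K) [n_in = %d]\n",
              x$slope, x$slope_se, x$cp0p, x$n_in))
  invisible(x)
}

#' Gamma-state validity check
#'
#' The diverging Gamma state predicts a linear temperature dependence of the
#' excess enthalpy (constant excess heat capacity).  Compares linear and
#' quadratic fits of `<U_pot> - <U_pot,bending>` by an F-test; the model
#' passes when the quadratic term is insignificant at `alpha`.
#'
#' @param series A [temperature_series()], at least 4 points.
#' @param alpha Significance level (default 0.05).
#' @return List of class `"gamma_validity"`: `pass`, `p_value`, `fits`.
#' @export
gamma_validity <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "temperature_series"), nrow(series) >= 4)
  series$y <- series$mean_U_pot - series$mean_U_bend
  w <- fit_weights(series$se_U_pot)
  f1 <- stats::lm(y ~ T, data = series, weights = w)
  f2 <- stats::lm(y ~ T + I(T^2), data = series, weights = w)
  an <- stats::anova(f1, f2)
  p <- an[["Pr(>F)"]][2]
  if (is.na(p)) p <- 1    # identical fits (exactly linear data)
  structure(list(pass = p > alpha, p_value = p, alpha = alpha,
                 fits = list(linear = f1, quadratic = f2)),
            class = "gamma_validity")
}

#' @export
print.gamma_validity <- function(x, ...) {
  cat(sprintf("Gamma-state linearity: %s (quadratic-term F-test p = %.3g, alpha = %g)\n",
              if (x$pass) "pass" else "FAIL", x$p_value, x$alpha))
  invisible(x)
}

#' Combined temperature-fit report
#'
#' Runs [fit_bending()], [fit_semiclassical()] and [gamma_validity()] on one
#' series and cross-checks `n_in` against `N - n_b` when the total internal
#' degree-of-freedom count is known.
#'
#' @param series A [temperature_series()].
#' @param n_in Semi-classical mode count (from [count_semiclassical()]).
#' @param N Optional total internal degrees of freedom for the cross-check.
#' @return List of class `"gamma_fit_report"`.
#' @export
temp_fit_report <- function(series, n_in, N = NULL) {
  bend <- fit_bending(series)
  semi <- fit_semiclassical(series, n_in)
  valid <- if (nrow(series) >= 4) gamma_validity(series) else NULL
  if (!is.null(N)) {
    n_in_fit <- N - bend$nb_int
    if (n_in_fit != n_in)
      warning("n_in from fits (N - n_b = ", n_in_fit,
              ") differs from the direct topological count (", n_in,
              "); the direct count is recommended")
  }
  structure(list(bending = bend, semiclassical = semi, validity = valid,
                 n_in = n_in),
            class = "gamma_fit_report")
}

#' @export
print.gamma_fit_report <- function(x, ...) {
  print(x$bending)
  print(x$semiclassical)
  if (!is.null(x$validity)) print(x$validity)
  invisible(x)
}
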