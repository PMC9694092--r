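---
title: "Gamma-state thermodynamics of flexible gas-phase molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-state thermodynamics of flexible gas-phase molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgethermo)
```

## The model

`qgethermo` computes the ideal-gas thermodynamics of a flexible molecule or
molecular complex along an isobar. The molecule's internal coordinates are
split once and for all into *quantum* modes (stretches and bends — high
force constants, treated as temperature-independent harmonic oscillators)
and *semi-classical* modes (torsions and, for complexes, inter-monomer
librations — the `n_in` lowest-frequency internal modes of the mass-weighted
Hessian). The semi-classical subsystem is described by the quasi-Gaussian
entropy (QGE) *diverging Gamma state*: its enthalpy-fluctuation distribution
is modelled as a Gamma distribution, which implies a constant excess
isobaric heat capacity $c'_{p0}$ and the closed forms

$$\mu'(p,T) = h'_0 - T_0 c'_{p0} + T (c'_{p0} - s'_0) + T c'_{p0}
\ln(T_0/T),$$
$$s'(p,T) = s'_0 + c'_{p0}\ln(T/T_0), \qquad
h'(p,T) = h'_0 + c'_{p0}(T - T_0), \qquad c'_p = c'_{p0},$$

anchored at a reference temperature $T_0$ — the lowest temperature at which
the torsions still behave semi-classically. Quantum-mode harmonic terms are
added on top ([`vib_thermo()`]), and all results are reported relative to
the reference-conformation enthalpy at $T = 0$
($h_\mathrm{ref}(0) = U_{e,\mathrm{ref}} + \mathrm{ZPE}$, with
$s_\mathrm{ref}(0) = 0$).

**Assumptions.** Ideal gas (single-molecule partition function); no
electronic excitations; frequencies temperature-independent; no mixing of
quantum and semi-classical coordinates across the temperature range; model
valid only for $T \ge T_0$ (evaluation below $T_0$ warns but proceeds, for
plotting).

## Parameterization

The anchors $(h'_0, s'_0)$ come from a sampling trajectory at $T_0$ plus
rigid-rotor/harmonic partition functions of a *reference conformation*:

1. **Reference basin** — frames are mass-weighted superposed, the Cartesian
   covariance is diagonalized, frames are projected on the two
   largest-variance eigenvectors, and the densest bin of a 2-D histogram
   marks the most-sampled basin (`select_reference_frame()`).
2. **Minimum and modes** — the chosen frame is energy-minimized
   (`minimize_structure()`); a central-finite-difference mass-weighted
   Hessian gives frequencies and eigenvectors with the six
   translation/rotation generators projected out (`normal_modes()`).
3. **Basin probability** — $P_\mathrm{ref}$ is the fraction of frames whose
   projections on every semi-classical eigenvector lie within $\pm k
   \sigma_{j,cl}$, $\sigma_{j,cl} = \sqrt{k_B T_0}/(2\pi\nu_{j,cl})$
   (`pref_estimate()`); then $\Delta\mu'_0 = -k_B T_0 \ln P_\mathrm{ref}$,
   $\Delta h'_0 = \langle U\rangle_{\mathrm{ref},0} - \langle U\rangle_0$
   and $\Delta s'_0 = (\Delta h'_0 - \Delta\mu'_0)/T_0$ (`md_deltas()`).
4. **k selection** — $k$ is the largest integer for which
   $\langle U\rangle_{\mathrm{ref},0} - U_{\mathrm{pot,ref}}$ matches the
   harmonic value $(N/2)k_B T_0$ within 2 (95%) or 3 (99.9%) standard
   errors (`select_k()`). Note a lower bound is intrinsic: restricting a
   harmonic mode to $\pm k\sigma$ lowers its mean potential energy by the
   truncated-Gaussian factor $1 - 2k\varphi(k)/(2\Phi(k)-1)$, which exceeds
   realistic noise for $k \le 2$; the criterion is therefore informative
   from $k \approx 3$ upward, which is also where the harmonic
   partition-function approximation for the basin becomes adequate.
5. **Anchors** — `excess_anchors()` assembles
   $\mu'_0 = -k_B T_0\ln(q_{rt}\,q_{in}) + k_B T_0 + k_B T_0\ln
   P_\mathrm{ref}$ and
   $h'_0 = U_{e,\mathrm{ref}} + \sum_j h\nu_{j,cl}/2 + \sum_j h\nu_{j,cl}\,
   e^{-\beta_0 h\nu_{j,cl}}/(1-e^{-\beta_0 h\nu_{j,cl}}) + 4k_BT_0 -
   \Delta h'_0$, with $s'_0 = (h'_0-\mu'_0)/T_0$ exact by construction.
   The translational/rotational partition function carries no stray factor
   of $e$; the $+k_BT_0$ term is applied explicitly in the $\mu'_0$
   assembly, which keeps the three anchor equations mutually consistent —
   the published form of the roto-translational partition function is
   typographically ambiguous on where that factor lives, and this is the
   only split under which the printed anchor equations close exactly.
6. **Heat capacity** — from trajectories at several temperatures,
   $\langle U_\mathrm{bend}\rangle(T)$ is fit quadratically (slope
   $\to n_b$, the bending count) and $\langle U\rangle -
   \langle U_\mathrm{bend}\rangle$ linearly; $c'_{p0} = \mathrm{slope} +
   (n_{in}/2 + 4) k_B$ (`fit_bending()`, `fit_semiclassical()`). The
   $(n_{in}/2+4)k_B$ constant is the kinetic equipartition of the
   semi-classical modes plus translational and rotational kinetic energy
   plus $pV$ — the same bookkeeping as the $4k_BT_0$ term of the enthalpy
   anchor; it is exposed as an argument (`kinetic_kB`) because the source
   equations never write the assembly explicitly. An F-test on the linear
   vs quadratic fit of the semi-classical energy (`gamma_validity()`) is
   the Gamma-state diagnostic: constant $c'_{p0}$ means linear excess
   enthalpy.

`fit_qge()` chains all stages and returns a classed model object with
`print`/`summary`/`coef`/`predict`/`plot` methods.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `T0` | 200 K | anchor temperature; lowest T where torsions are semi-classical |
| `p` | 1e5 Pa | pressure. "Standard state" is taken as 1 bar, not 1 atm; configurable |
| `k` | chosen by `select_k()` | box half-width multiplier, positive integer |
| `n_in` | from topology | dihedral count + libration count (6 for a two-body complex) |
| `gamma` | 0 | nuclear-permutation correction; rotational partition function carries 1/(1+γ). Per-system values are user input |
| `bins` | 50×50 | essential-dynamics histogram; densest-bin ties break to the lowest flattened index |
| Hessian step | 1e-4 nm | central differences, symmetrized (H+Hᵀ)/2 |
| roto-translational threshold | 1 cm⁻¹ | modes below it (after projection) are discarded; exactly 6 expected |

Units: kJ/mol, J/(mol K), cm⁻¹, K, Pa at the interfaces; nm/amu/ps
internally (CODATA 2018 constants), where kJ/mol ≡ amu nm²/ps² makes
mass-weighted Hessian eigenvalues ps⁻².

## The synthetic generator

`build_chain_model()` / `build_butane_like()` build united-atom chains with
fixed bond lengths (emulating constrained bonds — they appear as stiff
springs only in the Cartesian potential used for minimization and the
Hessian), harmonic bends ($k_\theta = 520$ kJ/mol/rad², $\theta_0 = 111°$,
typical force-field values), one multi-well backbone cosine torsion per
inner bond ($2.9(1+\cos\phi) + 5.92(1+\cos 3\phi)$ kJ/mol, a
trans/gauche topology with barriers of a few $k_BT$ at 200 K) and
single-well "methyl-like" rotor torsions ($7.5(1+\cos\phi)$) on the
terminal atoms. The butane-like default has $n_{in} = 3$ torsions and
$n_b = 2$ bends, so $N = 5$ internal degrees of freedom.

`mc_sample()` is Metropolis Monte Carlo in the internal coordinates — the
potential is separable, so each coordinate gets one uniform-step acceptance
decision per sweep, and torsion proposals are occasionally (p = 0.2)
replaced by an independent uniform draw over $(-\pi,\pi]$. The uniform
proposal is symmetric, so the chain stays exactly Boltzmann; without it,
trans↔gauche hops at 200 K are rare enough to bias a 10⁵-sweep estimate of
$P_\mathrm{ref}$ visibly (we verified the jump-augmented chain against
inverse-CDF iid sampling). The reference-temperature run is taken 2.5×
longer than the temperature-series runs, mirroring the usual practice of
protracting the $T_0$ trajectory to pin down $P_\mathrm{ref}$. Kinetic
contributions are never sampled; they enter analytically through the
$(n_{in}/2+4)k_B$ and $4k_BT_0$ terms, exactly as the model equations
prescribe.

What the generator does *not* emulate: inertial dynamics (no thermostat,
no time correlation in physical units), Jacobian factors of curvilinear
coordinates (the sampler and its oracles both use the flat internal-
coordinate measure, consistently), intramolecular nonbonded interactions,
and any claim of force-field realism. A green end-to-end test therefore
establishes that the estimators recover the generator's stated ground
truth — not that any real molecule is described.

## Oracles and numerical choices

* `quadrature_oracle()` integrates the Boltzmann weight per coordinate on a
  dense grid (periodic rectangle rule for torsions); `dU/dT` by central
  differences at $T\pm0.5$ K. For the in-box probability it has two modes:
  the uncoupled per-torsion product (exact when each semi-classical mode is
  one internal coordinate), and a direct grid quadrature over torsion space
  of the actual mode-space box indicator (frames reconstructed, superposed
  and projected exactly as `pref_estimate()` does). The second is the
  honest reference for the butane-like toy: its two rotor torsions are
  symmetry-degenerate, the Hessian eigenvectors mix them arbitrarily, and
  the box is then not axis-aligned in torsion space (true $P_\mathrm{ref} =
  0.853$ vs 0.839 for the uncoupled product at $k=3$, $T_0=200$ K).
* `harmonic_oracle()` gives the closed Gaussian forms
  $P_\mathrm{ref} = \mathrm{erf}(k/\sqrt2)^n$, $\langle U\rangle = (n/2)k_BT$
  and the truncated-box conditional mean.
* `block_se()` estimates standard errors of correlated series by block
  averaging with doubling block sizes, stopping at the plateau; it reduces
  to $\mathrm{sd}/\sqrt n$ for uncorrelated data. Binomial errors for
  $P_\mathrm{ref}$ use the indicator series' block SE (an effective sample
  size correction).
* Minimization: BFGS on flattened coordinates with finite-difference
  gradients, then Newton polishing with a finite-difference Hessian to
  max-gradient 1e-5 kJ/mol/nm. Degenerate inputs (identical frames, zero
  covariance) fall back to deterministic tie-breaks (frame 1, lowest bin
  index).

## Design choices made where the method left them open

* "Standard state" = 1 bar (1e5 Pa), configurable.
* γ defaults to 0; no symmetry-number detection from the molecular graph.
* Essential-dynamics superposition target is the first frame; bin grid
  50×50. Neither is prescribed by the method; both are recorded in the
  fit object.
* $\langle U\rangle_0$ averages over the *whole* reference trajectory,
  including in-box frames.
* The configuration file is JSON (`read_run_config()`): it round-trips
  numbers losslessly and matches the JSON outputs of the CLI.
* Frequency files are plain text, one wavenumber (cm⁻¹) per line, `#`
  comments.

## Limitations

* The published full-property values for real systems (e.g. the n-butane
  enthalpy at 300 K) require that system's quantum frequency list, which is
  supplementary data not shipped here; the package reproduces the excess
  (Gamma-state) part of those isobars exactly from the anchor table and
  the full properties once a frequency file is supplied.
* Linear molecules are unsupported in the rotational partition function
  (none of the intended systems are linear).
* No anharmonic quantum corrections, temperature-dependent frequencies,
  internal-rotor partition functions, or binary trajectory formats (xtc/
  trr); XYZ and GRO only.
* `select_k` at 10⁵-sweep precision resolves the toy's genuine
  anharmonicity: for the butane-like toy no k passes at either confidence
  level (the report says so rather than forcing a choice), while the fully
  harmonic toy passes from k = 3 up to the cap. Noisier data — like real
  MD — hides small anharmonic offsets and passes more readily; the
  diagnostic is doing its job in both cases.
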