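---
title: "Fluorescence-quenching analysis of protein–ligand binding with specbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence-quenching analysis of protein–ligand binding with specbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

## The measurement and its models

Serum albumin fluoresces when excited at 280 nm, mostly from its
tryptophan residues (bovine serum albumin has two, Trp 134 and Trp 212,
among its 583 residues), with an emission band near 345 nm. A ligand that
interacts with the protein quenches this emission, and the concentration
dependence of the quenching carries the binding information. `specbind`
analyses titrations in which the protein concentration is held fixed
(typically 5 µM) while the quencher is stepped from 0 to ~128 µM, repeated
at several temperatures.

### Stern–Volmer quenching

The intensity ratio follows

$$\frac{F_0}{F} = 1 + K_{sv}[Q] = 1 + K_q \tau_0 [Q],$$

where $F_0$ is the unquenched intensity, $K_{sv}$ the Stern–Volmer
constant and $\tau_0$ the unquenched fluorophore lifetime.
`stern_volmer_fit()` estimates $K_{sv}$ as the OLS slope of $F_0/F$
against $[Q]$ (the $Q=0$ point participates with $F_0/F = 1$), reports
$R^2$ as the squared Pearson correlation, and derives
$K_q = K_{sv}/\tau_0$. The default $\tau_0 = 10^{-8}$ s is the standard
lifetime scale for the Trp/Tyr/Phe fluorophores of albumins; it is a
configurable argument, and since $K_q$ is a deterministic rescaling of
$K_{sv}$, any other lifetime can be applied after the fact with
`bimolecular_rate()`.

Quenching can be *dynamic* (collisional: faster diffusion at higher
temperature raises $K_{sv}$) or *static* (ground-state complex: heating
destabilises the complex and lowers $K_{sv}$). `classify_mechanism()`
encodes this trend rule: the series is called dynamic when every
consecutive relative change of $K_{sv}$ exceeds $-\delta$ and the total
relative rise exceeds $+\delta$, static under the mirror rule, and
indeterminate otherwise. The default $\delta = 0.02$ (2 %) makes the
qualitative rule decidable on noisy estimates; it is exposed as
`rel_threshold`.

A frequently quoted heuristic holds that $K_q$ above the
diffusion-controlled limit $2\times10^{10}\,\mathrm{M^{-1}s^{-1}}$ implies
static quenching. In practice titrations can show $K_q$ orders of
magnitude above that limit while the temperature trend is clearly dynamic.
The package therefore computes the comparison but surfaces it only as the
advisory field `exceeds_diffusion_limit`; the mechanism call is always the
temperature-trend call. This keeps the two lines of evidence visible
without letting the heuristic silently override the data.

### Double-log binding fit

For a ligand occupying $n$ equivalent sites,

$$\log_{10}\frac{F_0-F}{F} = \log_{10} K_b + n \log_{10} [Q].$$

`double_log_fit()` runs OLS on the $Q>0$ points (the $Q=0$ point has no
defined logarithm), returning $K_b = 10^{\text{intercept}}$ and
$n = \text{slope}$. Points with $F \ge F_0$ carry no quenching signal and
are dropped with a warning. On noiseless collisional data the double-log
and Stern–Volmer fits coincide exactly: $K_b = K_{sv}$, $n = 1$ — a
useful algebraic cross-check that the test suite exercises.

A caution that the package's own simulations make vivid: $K_b$ is the
*extrapolation* of the double-log line to $[Q] = 1$ M, about five decades
beyond a micromolar titration. At low $[Q]$ the quenched fraction is a
difference of two nearly equal intensities, so even 1 % multiplicative
intensity noise produces order-of-magnitude scatter in $K_b$ while $K_{sv}$
(estimated near the data) stays within a few percent. $n$ and $K_{sv}$ are
the robust quantities; $K_b$ from this method should be read on the log
scale. `n` is reported unrounded; a value near 1 is conventionally read as
a single binding site.

`classify_affinity()` brackets $K_b$ against the range
$1\text{–}15\times10^4\ \mathrm{M^{-1}}$ (boundaries inclusive) that marks
average, reversible transport binding to albumin.

### Van't Hoff thermodynamics

With $K_b$ measured at three or more temperatures,

$$\log_{10} K_b = -\frac{\Delta H}{2.303\,R\,T} + \frac{\Delta S}{2.303\,R},
\qquad \Delta G = \Delta H - T\,\Delta S,$$

with $R = 8.314\ \mathrm{J\,K^{-1}mol^{-1}}$. `vant_hoff_fit()` regresses
$\log_{10} K_b$ on $1/T$; the factor is the literal 2.303 of the
conventional notation, used identically in the generator
(`simulate_kb_series()`) so the round trip is exact to machine precision.
Internally all energies are J/mol and J/(mol K); only the report layer
converts to kJ. This avoids a classic unit trap: entropy values printed as
"0.019" in a J-column are only consistent with their $\Delta G$ column on
the kJ scale. `vant_hoff_consistency()` is provided exactly for such
cases — it refits the $K_b$ series and flags reported $\Delta H$/$\Delta S$
values that the series cannot reproduce (default tolerance 10 %), rather
than guessing which value was intended.

`classify_forces()` applies the standard sign rules
(Ross–Subramanian): $\Delta H>0,\Delta S>0$ → hydrophobic;
$\Delta H<0,\Delta S<0$ → van der Waals / hydrogen bonding;
$\Delta H<0,\Delta S>0$ → electrostatic. The dead-band tolerances
(1 J/mol, 0.01 J/(mol K)) only guard estimates numerically
indistinguishable from zero. `spontaneity()` is strict negativity of
$\Delta G$; the boundary value 0 is non-spontaneous.

### Site-marker displacement

`site_marker_analysis()` compares $K_b$ measured alone with $K_b$
re-measured in the presence of site-specific markers (ranitidine for
Sudlow site I, ibuprofen for site II). The marker causing the largest
relative reduction $r_i = 1 - K_{b,i}/K_{b,\text{free}}$ shares the
ligand's pocket. If the top two reductions differ by less than `tie_tol`
(default 0.05) the assignment is indeterminate instead of arbitrary.

### Spectral probes of conformational change

All probes build on a small feature-extraction core:

- `peak_max()` locates the sampled maximum and refines interior peaks by
  the vertex of the parabola through the three surrounding samples (ties
  break toward lower wavelength; a non-concave triple falls back to the
  sample). On a Gaussian band sampled at 1 nm this recovers an on-grid
  centre exactly and an off-grid centre to a few hundredths of a
  nanometre.
- `band_shift()` is the signed difference of two peak locations — e.g. the
  −14 nm blue shift of the emission band (345 → 331 nm) that indicates
  increased hydrophobicity around the fluorophore, or the +2 cm⁻¹ amide-I
  shift (1636 → 1638 cm⁻¹) in the infrared.
- `synchronous_scan()` extracts $S(\lambda_{ex}) = z(\lambda_{ex},
  \lambda_{ex}+\Delta\lambda)$ from an excitation–emission matrix with
  linear interpolation along the emission axis, restricted to excitations
  whose target is covered. $\Delta\lambda = 15$ nm reads the tyrosine
  channel, 60 nm the tryptophan channel.
- `eem_peaks()` reports 8-neighbourhood local maxima of the EEM after
  masking the first-order ($|em-ex|\le w$) and second-order
  ($|em-2\,ex|\le w$) Rayleigh ridges. The half-width default $w = 10$ nm
  covers a 5 nm slit. Masked cells cannot be peaks but still participate
  in neighbour comparisons, so ridge flanks are not reported as spurious
  maxima.
- `absorbance_trend()` classifies the titration trend of absorbance at a
  probe wavelength (280 nm default) by the sign of the OLS slope against
  titration index, with relative end-to-end changes under 1 % reported as
  "none" — a tolerance needed only because the underlying call is
  qualitative.
- `cd_estimate()` converts an ellipticity reading to mean residue
  ellipticity, $\mathrm{MRE} = \theta_{mdeg} / (10\,l\,c\,N)$, and applies
  the standard single-wavelength helix estimate at 208 nm,
  $h = 100\,(-\mathrm{MRE}_{208} - 4000)/29000$, clamped to $[0,100]$.
  The endpoints −4000 (coil) and −33000 (helix) make the estimate
  invertible, which is what allows exact round-trip testing. Basis-set CD
  deconvolution (sheet/turn fractions) is deliberately out of scope: those
  quantities come from proprietary instrument software and are not
  reproducible from a single spectrum.

`conformational_report()` folds the probe readings into one structured
summary with rule-based interpretations (Trp channel shifted / Tyr channel
still / blue shift / hypochromicity / amide shift / helix loss); shifts
below 0.5 nm — beneath a 1–2 nm instrument step — are treated as zero.

## The synthetic-data generator

Every analysis stage has a generator with known truth
(`truth_params()`, `simulate_titration()`, `simulate_emission_spectrum()`,
`simulate_eem()`, `simulate_kb_series()`, `simulate_cd_spectrum()`), so
correctness is established by parameter recovery rather than by fixture
files. Design choices:

- **Defaults are the study design**: 5 µM protein; quencher grid
  {0, 2, 4, 8, 16, 32, 64, 128} µM (a doubling ladder spanning the stated
  0–128 µM range); temperatures {298, 303, 308, 318} K; excitation 280 nm,
  observation 345 nm; emission band moving 345 → 331 nm at full quenching;
  EEM grids ex 230–330 / em 280–420 nm at 2 nm (axis spans fixed by
  convention); CD bands at 208/222 nm measured at 2.5 µM, 583 residues,
  0.1 cm path.
- **Noise is multiplicative Gaussian per point**, `F·(1+ε)`,
  `ε ~ N(0, σ)`, seeded and independent: photomultiplier noise scales
  with signal. With σ = 0 every generated point satisfies its defining
  model equation to machine precision, which the suite asserts for all
  four titration models.
- **Seeding is local**: generators set the RNG from their own seed and
  restore the caller's stream, so simulations are bit-reproducible without
  side effects.
- The static model uses the same single-temperature functional form as the
  dynamic one (they are indistinguishable at one temperature); the
  discrimination lives entirely in the temperature trend, which a
  `thermo_truth()` with negative enthalpy can drive downward.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: inner-filter attenuation at high
quencher absorbance, fluorophore lifetime heterogeneity, instrument
baseline drift, wavelength-dependent detector response, and real CD band
shapes beyond two Gaussians. The fits themselves are unweighted OLS with
no robust refitting, matching the conventional treatment; they will not
down-weight a bad titration point.

## Numerical choices and degenerate inputs

- All logarithms in fits and generators are base 10 with the literal
  conventional factor 2.303 (not $\ln 10$), consistently on both sides, so
  generator→fit round trips are exact.
- A titration with constant intensity gives a `"degenerate"`-flagged
  Stern–Volmer fit with $K_{sv}=0$ rather than an error; a rising
  intensity gives a `"negative_slope"` flag. Errors are reserved for
  structurally unusable input (fewer than 3 points, non-monotone grids,
  non-positive intensities).
- `peak_max()` on an all-equal window raises a degenerate-peak error;
  boundary maxima are returned unrefined.
- Problem sizes in the test suite and acceptance script are the study's
  own: 8-point titrations, 4 temperatures, 200-seed recovery batches,
  ~50×70 EEM grids — everything runs in seconds.

## Known limitations

- $K_b$ from the double-log method is an extrapolated intercept and is
  noise-fragile (see above); the package reports it as the method defines
  it and leaves robust alternatives (global nonlinear fits, lifetime
  analysis) out of scope.
- The mechanism rule and force rules are the field's qualitative
  conventions made decidable by explicit thresholds; borderline data
  yield `"indeterminate"` rather than a forced call.
- Reported thermodynamic tables whose $\Delta S$/$\Delta G$ columns are
  mutually inconsistent with their $K_b$ series cannot be reconciled by
  computation; `vant_hoff_consistency()` flags, and the report prints,
  both readings without guessing.
- Docking and molecular-dynamics evidence for site assignment is a
  different kind of computation entirely and is outside this package.
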