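---
title: "Quantifying ligand binding to DNA and plasma proteins from titration spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ligand binding to DNA and plasma proteins from titration spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

specbind analyzes the two workhorse experiments of solution-phase
binding studies on small drug-like ligands: UV-Vis absorbance titrations
against DNA, and fluorescence quenching titrations against DNA probes or
plasma proteins. Every estimator takes a tidy table of
(concentration, signal) readouts — or a `titration_series` of full spectra —
and returns a fitted object with broom-style `tidy()`/`glance()` methods and
an `autoplot()` diagnostic figure. This vignette explains the models behind
each estimator, the assumptions they make, the defaults and why they were
chosen, and what the synthetic-data generator does and does not emulate.

## From spectra to readouts

A `titration_series` holds a zero-titrant *base* spectrum (supplying $A_0$
or $F_0$) plus one spectrum per titrant addition. Two deliberate rigidities:

* **Exact shared wavelength grids.** Instrument exports of one titration
  share a grid; a mismatch signals an acquisition or parsing problem, so the
  constructor raises a grid error rather than silently interpolating.
* **Fixed readout channel.** With the `peak_max` policy the readout
  wavelength is chosen *on the base spectrum* and held fixed for every
  titration point. Quenching or chromism therefore cannot walk the readout
  channel across the band. Ties between equal maxima break to the smallest
  wavelength, so the choice is deterministic. Emission values are taken at
  the single peak channel; whether a narrow band average is preferable is
  instrument-dependent, so a `band_nm` option exists but defaults to off.

Concentrations are molar everywhere; molar ratios that appear in reports
are derived on the fly, never stored, which avoids mixing unit systems.

## UV-Vis association: chromism and the Benesi–Hildebrand plot

Complexation of a ligand with DNA changes its absorption band. The percent
chromism is $(A_0 - A)/A_0 \times 100$. Because a *hyper*chromic effect
(absorbance rising) makes this expression negative while such tables are
conventionally printed with positive magnitudes, `chromism()` reports the
signed value, the magnitude and a direction flag instead of collapsing the
two conventions.

For a 1:1 complex with association degree
$\alpha = K_{app} c/(1 + K_{app} c)$, the observed absorbance is
$A(c) = (1-\alpha) A_0 + \alpha A_c$ and the double-reciprocal form

$$\frac{1}{A_{obs} - A_0} = \frac{1}{A_c - A_0}
  + \frac{1}{K_{app}(A_c - A_0)}\cdot\frac{1}{c}$$

is linear in $1/c$. `benesi_hildebrand()` fits it by ordinary least
squares; $K_{app}$ is the intercept/slope ratio, with a delta-method
standard error from the coefficient covariance. Two failure modes are
detected rather than propagated: a point with $A_{obs}=A_0$ (the reciprocal
is singular; the offending concentration is named) and mixed signs of
$A_{obs}-A_0$ (the titration is not moving monotonically toward one
complex). The Gibbs energy follows as $\Delta G^\circ = -RT\ln K_{app}$
with $R = 8.314$ J mol$^{-1}$K$^{-1}$, reported in J/mol — the magnitude of
$-RT\ln K$ for a $10^3$ M$^{-1}$ constant is $\sim 2\times10^4$, which is
only consistent with J/mol even where such tables label the column kJ/mol.

`classify_uvvis_mode()` encodes the magnitude argument used to call a
binding mode from $K_{app}$ alone: constants of order $10^2$–$10^3$
M$^{-1}$ are far below those of classical intercalators (ethidium bromide:
$1.23\times10^5$ M$^{-1}$), so values below $10^4$ are called
groove-or-mixed, values at or above $10^5$ intercalation-likely, and the
band in between groove-or-mixed with an indeterminacy flag. Both bounds are
arguments.

## Fluorescence quenching

Before any quenching fit, observed intensities must be corrected for the
inner filter effect — re-absorption of excitation and emission light —
via $F = F_{obs}\,10^{(A_{ex}+A_{em})/2}$. The correction is applied only
when per-point absorbances are available (a series carries them after
`gen_inner_filter()`, or they can be supplied directly); when they are
absent the series passes through unchanged with a notice, because inventing
absorbances would bias every constant downstream.

`stern_volmer()` fits $F_0/F = 1 + K_{SV}[Q]$ by OLS. The intercept is
*fitted*, not pinned at 1: a deviation beyond 10% warns, since it usually
means a wrong $F_0$ or curvature outside the linear range. The bimolecular
quenching rate constant is $k_q = K_{SV}/\tau_0$ with $\tau_0 = 6$ ns, the
average fluorescence lifetime appropriate for the plasma proteins targeted
here. $k_q$ above the aqueous diffusion limit of $2\times10^{10}$
M$^{-1}$s$^{-1}$ implies ground-state complex formation (static quenching);
`quench_mechanism()` applies that threshold, treats the exact boundary as
indeterminate, and reports whether $K_{SV}$ falls with temperature — a
corroborating, not required, sign of the static mechanism.

Three DNA-side assays reuse the same machinery:

* `displacement()` — percent exchange $(F_0-F)/F_0\times100$ of a
  DNA-bound probe (ethidium bromide) displaced by a competitor;
* `ki_protection()` — the reduction in the iodide-quenching $K_{SV}$ of a
  ligand when DNA is present. An intercalated fluorophore is shielded from
  the anionic quencher, so reductions at or above 45% (configurable) are
  intercalation-consistent and smaller ones indicate groove or mixed
  binding;
* `ionic_strength_trend()` — the sign of the OLS slope of $F/F_0$ versus
  added NaCl. Rising fluorescence with salt means the cation displaces the
  ligand from an electrostatic site. Qualitative trend arguments are made
  reproducible with a conventional $|$slope$| > 2\,\mathrm{SE}$ significance
  rule; that rule is a package convention, not an experimental standard.

## Binding constants and thermodynamics

For static quenching by complex formation the double-logarithm model

$$\log_{10}\frac{F_0 - F}{F} = \log_{10} K_b + n\,\log_{10}[Q]$$

gives the binding constant and the number of binding sites from an OLS
line. `double_log_fit()` maintains $K_b = 10^{\log K_b}$ as an exact
identity and keeps $n$ as the fitted exponent without rounding it to an
integer. Points with $F \ge F_0$ are rejected by name: their logarithm is
undefined, and in practice they flag an $F_0$ mismatch.

`vant_hoff()` regresses $\ln K_b$ on $1/T$:
$\ln K_b = -\Delta H^\circ/(RT) + \Delta S^\circ/R$. The natural-logarithm
form is used because it is the one for which $R$-scaled slope and intercept
are dimensionally correct; a $\log_{10}$ plot would need an extra
$\ln 10$ factor that printed tables in this field rarely make explicit.
With only three temperatures (297, 303, 308 K is the common design) the
enthalpy is assumed constant over the 11 K window — a nonlinear
(temperature-dependent $\Delta C_p$) treatment is out of scope.

Two routes give $\Delta G^\circ$ at the reference (lowest) temperature:
$\Delta H^\circ - T\Delta S^\circ$ and $-RT\ln K_b$. They agree only as
well as the fit is good, so `gibbs_report()` computes both and labels which
one is reported; the enthalpy route is the default because it is the one
that printed thermodynamic tables in this literature reproduce.
`interaction_forces()` applies the Ross–Subramanian signature rules:
both signs negative — hydrogen bonds and van der Waals contacts; both
positive — hydrophobic; $|\Delta H^\circ| < 4$ kJ/mol with positive
entropy — electrostatic; anything else mixed.

## The binding-mode verdict

`binding_verdict()` turns the per-assay classifications into one call,
formalizing reasoning that is usually narrative: intercalation is called
only when *both* the association-constant test and the iodide-protection
test point to it (a veto, since either alone is ambiguous); an
electrostatic component reported by the salt assay annotates the verdict
(or becomes it when nothing groove-consistent remains); otherwise
groove-consistent votes are counted against the displacement flag
(probe exchange above 20%). All thresholds are config-overridable in
`run_pipeline()`, and every fired rule is logged, so the verdict is
deterministic and auditable.

## What the synthetic generator emulates — and what it does not

The generators exist so that every estimator is testable by parameter
recovery without instrument data:

* `gen_uvvis()` draws the 1:1 isotherm exactly at the readout channel;
* `gen_quench()` draws either the Stern–Volmer law or the log-linear law
  $(F_0-F)/F = K_b[Q]^n$ — the latter is the canonical ground truth for
  double-log recovery because the model is exact for it, so estimator error
  is never confounded with model misfit. The generating law is recorded in
  the series metadata so a test cannot silently fit the wrong one;
* `gen_inner_filter()` attenuates by $10^{-(A_{ex}+A_{em})/2}$, making the
  correction an exact inverse pair;
* `gen_vant_hoff()` produces constants with exact van't Hoff temperature
  dependence.

Noise is additive Gaussian on intensities (1% of the base signal by
default — a typical photometric noise floor; the choice is free since no
instrument noise model is prescribed), applied to every channel, seeded,
and scoped so the global RNG stream is untouched. Band shapes are single
Gaussians: only the readout channel is physically modelled, all other
channels are decorative. Real spectra differ in ways the generator does not
attempt: band overlap and shifts on binding, baseline drift, scatter,
dilution of the fixed species, and correlated (not channel-independent)
noise. Passing recovery tests therefore demonstrates estimator
correctness under the stated laws, not robustness to those artifacts.
Absorbance channels are clamped at zero after noise, which only affects
decorative band tails.

Default titrant designs mirror common laboratory conditions: DNA at
12.5–75 µM against a 50 µM ligand for UV-Vis (molar ratio 0.25–1.5), and
quencher at 0.2–2.0 µM against a 1.0 µM protein (ratio steps of 0.2) at
297/303/308 K.

## Numerical choices and calibration of the recovery suite

All fits are OLS on the linearized forms (`stats::lm`), matching how these
plots are analyzed in practice; no weighting is applied. The reciprocal and
logarithmic transforms amplify noise wherever the bound fraction is small,
so the 1%-noise recovery checks in the test suite use regimes chosen by
signal-to-noise reasoning, with at least 8 points per titration and 200
seeded replicates each, asserting that the *median* recovered constant
falls within 5% of truth (and the median van't Hoff enthalpy error under
10%): the double-reciprocal constant is five-to-ten times more variable
per titration than a direct isotherm fit would be, which is a property of
the linearization, not of the implementation. The test suite also checks
the Benesi–Hildebrand line against an independent grid-search nonlinear
least-squares of the isotherm, and the van't Hoff line against the
two-temperature closed form. Zero-noise recovery is asserted to a relative
error of $10^{-9}$, i.e. linear-algebra precision.

Degenerate inputs fail loudly: constant absorbance differences (zero
slope), singular reciprocal points, non-positive fluorescence, fluorescence
at or above $F_0$, single-temperature van't Hoff input, and readout windows
outside the wavelength grid each raise a classed error.

## Known limitations

* Only 1:1 stoichiometry for the absorbance isotherm; no cooperative or
  multi-site absorbance models.
* No combined static-plus-dynamic (sphere-of-action) quenching model; the
  mechanism call rests on the $k_q$ threshold and the temperature trend.
* No error-in-variables regression: concentrations are treated as exact.
* The reference tables shipped with the package carry printed (rounded)
  constants; quantities recomputed from them inherit that rounding, which
  is why one published Gibbs energy (AAG, compound 4) is reproduced by
  neither defining route and is documented as an exception rather than
  reconciled.
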