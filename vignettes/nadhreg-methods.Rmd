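---
title: "Models and numerical methods in nadhreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in nadhreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadhreg)
```

`nadhreg` implements the computational chain used to characterise the
[Cp*Rh(bpy)Cl]⁺-mediated electrochemical regeneration of active 1,4-NADH:
voltammetric kinetics, equivalent-circuit impedance analysis, the
enzyme-coupled two-wavelength assay, and the derived regeneration metrics.
This vignette documents the underlying models, the assumptions each one
makes, the numerical choices, and what the synthetic-data generators do and
do not emulate.

## Peak-shift kinetics of irreversible electron transfer

For a one-step, totally irreversible reduction the cathodic peak potential
depends on scan rate $\nu$ (Nicholson–Shain theory):

$$\frac{\mathrm{d}E_p}{\mathrm{d}\log_{10}\nu}
  = -\ln(10)\,\frac{RT}{2\,\alpha n F},$$

so an ordinary least-squares regression of $E_p$ on $\log_{10}\nu$
(`peak_shift_fit`) recovers the transfer-coefficient product
$\alpha n = \ln(10)\,RT/(2F\,|\text{slope}|)$. At 293 K the proportionality
constant is `peak_shift_constant(293)` $\approx 0.029$ V/decade. A
*numerical choice*: the exact $\ln(10) = 2.302585\ldots$ is used rather
than the conventionally quoted rounded factor 2.303, so that the decade-log
regression route and the natural-log two-point formula
(`two_point_alpha_n`) agree to machine precision; the difference is below
0.02 % and invisible at the two decimals to which $\alpha n$ is usually
reported.

Assumptions: planar semi-infinite diffusion, full kinetic control of the
peak (no ohmic drop, no adsorption), and a potential-independent $\alpha$.
The model applies to the first NAD⁺ reduction peak and to the mediator
reduction peak; it is *not* valid for reversible couples (peak-separation
diagnostics are out of scope).

Peak detection (`detect_peaks`) fits a straight baseline to a pre-peak
"foot" region — by default the 30 % of the sweep immediately preceding the
search window, a choice the analysed experiments do not prescribe — and
subtracts it before locating the extremum. A centred moving average
(default 5 points, odd) is used *only* to localise the extremum; the
reported peak current is the unsmoothed baseline-corrected value, so
smoothing cannot attenuate $i_p$. Equal-current plateaus report the plateau
midpoint. Peaks below a prominence floor
($\max(\texttt{min\_prominence},\,10^{-12}\max|i|)$) are treated as
numerical noise. Because the baseline is itself linear in the data, adding
any straight line to the current leaves both $E_p$ and $i_p$ unchanged — a
property the test suite asserts.

## Equivalent circuits and effective capacitance

Impedance spectra are described by expression trees over three passive
elements ($\omega = 2\pi f$):

$$Z_R = R,\qquad
  Z_{CPE} = \frac{1}{Y_0 (j\omega)^n},\qquad
  Z_W = \frac{1}{Y_w\sqrt{j\omega}},$$

composed by series/parallel nodes. Four presets cover the observed
behaviour of glassy-carbon electrodes at increasing cathodic bias:

| preset | topology | regime |
|---|---|---|
| `EEC_A` | $R_s + (CPE \parallel R_p)$ | single time constant |
| `EEC_B` | $R_s + (CPE \parallel (R_p + W))$ | charge transfer under diffusion |
| `EEC_C` | $R_s + (CPE_1 \parallel (R_1 + (CPE_2 \parallel (R_2 + W))))$ | film forming, diffusion-limited |
| `EEC_D` | $R_s + (CPE_1 \parallel (R_1 + (CPE_2 \parallel R_2)))$ | completed dual layer |

The pictured circuits do not fix the branch of the Warburg element in the
two-time-constant case; placing it in the *inner* mesh of `EEC_C` is an
assumption of this package (the outer-mesh variant is expressible with the
same algebra if needed). Only the semi-infinite Warburg form is provided —
no bounded-diffusion thickness is identifiable from the data this package
targets.

Fitting (`fit_circuit`) minimises the weighted sum of squared real and
imaginary residuals (modulus weighting $1/|Z|$ per point by default; unit
and proportional weighting are configuration options) with
Levenberg–Marquardt (`minpack.lm`). Optimisation runs in log-parameter
space (logit space for CPE exponents), so positivity and $n \in (0,1]$
hold by construction. Starting values come from the spectrum itself: the
high-frequency real-axis minimum for $R_s$, the low-frequency limit for the
polarization resistances, $|Z|$ near 1 kHz for $Y_0$; eight seeded
log-normal restarts around that guess guard against local minima. Standard
errors are delta-method transforms of the LM covariance.

`select_model` ranks candidates by AICc computed over the $2m$
real/imaginary residuals with parameter-count penalty; the weighted RSS is
floored at $m \times 10^{-28}$ so that machine-exact fits are separated by
parsimony rather than floating-point noise, and remaining ties break toward
fewer parameters.

Each $CPE \parallel R$ motif yields an effective capacitance

$$C_\mathrm{eff} = \frac{(Y_0 R_p)^{1/n}}{R_p}\,\sin\!\frac{n\pi}{2},$$

which reduces to $C_\mathrm{eff} = Y_0$ at $n = 1$ and is monotone
increasing in $Y_0$.

## The two-wavelength assay

The assay prepares five solutions from the regeneration electrolyte at a
fixed 0.8 dilution; lactate dehydrogenase consumes exactly the active
1,4-NADH between cuvettes D (before) and E (after). Since only the Rh
mediator absorbs at 430 nm, the inversion proceeds in four steps
(`quantify_nadh`): the mediator change
$\Delta c_{Rh} = ((D_{430}-E_{430})/0.8 - b_{Rh,430})/m_{Rh,430}$; its
340 nm contribution
$\Delta Ext_{Rh,340} = (\Delta c_{Rh}\, m_{Rh,340} + b_{Rh,340})\cdot 0.8$;
the active-species extinction
$Ext_{340} = D_{340} - E_{340} - \Delta Ext_{Rh,340}$; and finally
$c_{1,4\text{-NADH}} = (Ext_{340}/0.8 - b_{NADH,340})/m_{NADH,340}$.

Two deliberate choices: the mediator-correction formula is applied *as
printed*, including its offset term even when $\Delta c_{Rh} = 0$ (set
`strict_rh_offset = FALSE` to drop the offset in that case, where "zero" is
tested at $10^{-12}$ mM to absorb calibration round-off); and negative
concentrations are reported with a warning rather than clamped — silent
clamping would hide assay failure.

Selectivity is the fraction of 340 nm absorbance due to active 1,4-NADH
among all NAD reduction products. The denominator is taken as
$B_{340} - A_{340}$ (regenerated solution minus pre-regeneration
electrolyte, same dilution) because NAD⁺ itself does not absorb at 340 nm;
whether the "electrolyte" blank is read before or after regeneration is an
interpretation, so the raw $D-E$ denominator is available as
`selectivity_mode = "D_minus_E_uncorrected"`. Note the selectivity is an
*absorbance* fraction: the inactive isomers and the NAD₂ dimer have molar
absorptivities different from 1,4-NADH, so it is not a mole fraction; no
correction is attempted. Values outside $[0,1]$ are clamped with a warning.

Faraday efficiency is $\eta_F = Q_{theo}/Q_{total}$ with
$Q_{theo} = z F n_{NADH}$ and $z = 2$: the hydride equivalent transferred
to NAD⁺ carries two electrons. $Q_{total}$ is the trapezoidal integral of
$|i|$ over the whole record, initial capacitive transient included (an
optional cutoff can exclude it, but by default nothing is discarded — the
transient is genuinely passed charge). The specific production rate is
fixed to µmol h⁻¹ cm⁻², i.e. $n_{NADH}\cdot 10^6/(A\,t/3600)$.

## The voltammetry simulator

`simulate_irreversible_cv` solves

$$\frac{\partial c}{\partial t} = D\frac{\partial^2 c}{\partial x^2},
\qquad
D\frac{\partial c}{\partial x}\Big|_{x=0}
 = k_0\, c(0,t)\, e^{-\alpha n F (E - E^{0\prime})/RT},$$

on a triangular potential programme. Numerics: backward-Euler time steps of
one potential increment `dE` (default 1 mV, i.e. `dE/ν` seconds), an
exponentially expanding spatial grid whose first cell is `h0` (default
0.05) of the kinetic reaction layer $\sqrt{DRT/(\alpha n F \nu)}$ with
expansion factor 1.15, and a simulation box of $6\sqrt{D\,t_{total}}$
closed by a Dirichlet bulk boundary — about 40 spatial nodes in practice.
The implicit scheme is unconditionally stable; an explicit scheme is
provided for cross-checking and raises a structured error naming the
violated bound $\Delta t \le 1/\max_j\!\big(2D/(h_l h_r)\big)$ when the
grid would be unstable.

A useful property of this discretisation: in the dimensionless variables
$\tau = \alpha n F \nu t/RT$, $\xi = x\sqrt{\alpha n F\nu/(RT\,D)}$ the
stepping is *identical across scan rates* (both $\Delta\tau$ and the
dimensionless grid depend only on `dE` and `h0`), so discretisation error
cancels almost exactly in the peak-shift slope — the acceptance suite
measures the simulated slope within 0.2 mV/decade of the closed form, far
inside the 2 mV/decade requirement, and $i_p \propto \sqrt{\nu}$ within
2 % across a decade.

Default kinetic parameters (`cv_truth`): $\alpha n = 0.49$,
$k_0 = 10^{-4}$ cm/s, $E^{0\prime} = -0.88$ V, $D = 5\times10^{-6}$ cm²/s,
5 mM analyte, 293 K, a 2 mm rod electrode. $D$ and $k_0$ are placeholders
recorded in every truth sidecar — no measured values exist for this system
— chosen so the simulated NAD⁺ peak falls in the observed −1.06 … −1.16 V
range over $\nu \in [0.025, 1]$ V/s. The catalytic variant
(`simulate_catalytic_cv`) adds a single pseudo-first-order regeneration of
the oxidised species from the product (exact exponential operator
splitting, unconditionally stable); it is a deliberate caricature of the
multi-step mediated cycle, useful only for its qualitative properties
(reduction to the base case at $k=0$, monotone peak amplification).

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure the analysis assumes*:
proportional Gaussian noise (the only noise family offered) on currents,
impedances and extinctions, seed-controlled and restoring the global RNG
state. `make_bundle` builds a full experiment whose truth is internally
consistent by construction: the inactive-species concentration is solved
from the configured selectivity, and the faradaic current from the
configured Faraday efficiency, so that $Q_{theo}/Q_{total}$ equals the
configured $\eta_F$ to $10^{-12}$ before noise. The chronoamperogram truth
quotes the capacitive charge as the trapezoidal integral on the sampling
grid — the same quadrature the analysis applies — so noiseless round trips
are exact rather than exact-up-to-quadrature.

Defaults mirror the regeneration protocol: 1800 s potentiostatic runs at
−0.75 V, a 4 cm² plate electrode, 20 mL of electrolyte, 0.25 mM mediator,
0.1 V/s voltammograms over 0 → −1.8 → 1 → 0 V, 0.2 mM regenerated active
NADH, and assay extinction coefficients of 6.3 mM⁻¹ (1,4-NADH, 340 nm),
5.0 mM⁻¹ (inactive pool, 340 nm — a plausible mid-range value, as the
isomer mix is unknown), 0.2/0.5 mM⁻¹ (mediator at 340/430 nm).

What the generators do **not** emulate — and therefore what passing tests
do *not* establish about laboratory data: hydrogen-evolution background
currents, mediator adsorption and electrode blocking, drift or
non-stationarity in impedance spectra, baseline curvature from overlapping
waves, buffer effects, and the instability of NADH species in unsuitable
buffers. Experimentally headline values (such as near-unity selectivity at
optimal pH) depend on deposited laboratory data and are outside what
synthetic round trips can certify; the pipeline's correctness claims are
confined to recovering known synthetic truth.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: six scan rates
(0.025–1 V/s) at 1 mV steps for simulator validation; 61-point frequency
grids (0.1 Hz – 100 kHz, 10 points/decade) with 20 noisy replicates per
circuit preset; 100 assay noise seeds; and 1–2 s sampling of 1800 s
chronoamperograms. These sizes give sub-percent Monte-Carlo error on every
reported median while keeping a full run in well under a minute on a single
core.

## Known limitations

* Ohmic-drop correction, reversible/quasi-reversible peak diagnostics and
  semi-integral voltammetry are not implemented.
* Kramers–Kronig validation of impedance spectra is limited to a
  passivity sanity check ($\mathrm{Re}\,Z > 0$ for all presets).
* The assay inversion propagates no calibration uncertainty into
  $c_{1,4\text{-NADH}}$; errors are assessed empirically by seeded noise
  studies instead.
* File input is limited to delimited text with an explicit column map;
  proprietary potentiostat formats are out of scope.
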