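# nadhreg

Electroanalytical toolkit for the mediated electrochemical regeneration of
the enzymatic cofactor 1,4-NADH.

## The problem

NADH-dependent oxidoreductases are only viable at scale if the consumed
cofactor is regenerated in situ. Electrochemical reduction of NAD⁺ mediated
by the rhodium complex [Cp*Rh(bpy)Cl]⁺ is the most selective route to the
enzymatically *active* 1,4-NADH isomer — direct electroreduction instead
produces mostly inactive 1,2-/1,6-NADH and the NAD₂ dimer. Assessing such a
regeneration system requires a chain of standard but error-prone
electroanalytical computations, which this package implements as tested,
reusable building blocks for electrochemists and bioprocess engineers:

* **Voltammetric kinetics.** For a totally irreversible reduction the
  cathodic peak potential shifts with scan rate ν as

  ```
  dE_p / dlog10(ν) = −2.303·R·T / (2·α·n·F)
  ```

  so an ordinary least-squares fit of `E_p` against `log10(ν)` yields the
  transfer-coefficient product αn (`peak_shift_fit`, `two_point_alpha_n`),
  while `i_p ∝ √ν` diagnoses diffusion control (`scan_rate_current_fit`).
  Peaks are located with linear pre-peak baselines (`detect_peaks`).
* **Impedance analysis.** A small circuit algebra (R, constant-phase
  element, semi-infinite Warburg; `ckt_*`, `eec_preset`) with a recursive
  forward model (`impedance_of`), complex nonlinear least-squares fitting
  in log-parameter space (`fit_circuit`), information-criterion model
  ranking (`select_model`), and the effective capacitance of a CPE∥R motif,
  `C_eff = (Y₀·R_p)^(1/n) / R_p · sin(nπ/2)` (`effective_capacitance`).
* **Active-NADH assay.** The two-wavelength, five-solution
  lactate-dehydrogenase scheme: the 430 nm D−E difference isolates any
  mediator change between cuvettes, its 340 nm contribution is subtracted,
  and the remaining 340 nm difference is converted to the active 1,4-NADH
  concentration through linear calibration curves (`quantify_nadh`,
  `fit_calibration`), all at the scheme's fixed 0.8 dilution.
* **Regeneration metrics.** Selectivity (the 340 nm absorbance fraction of
  active 1,4-NADH among all reduction products), Faraday efficiency
  `η_F = Q_theo/Q_total` with `Q_theo = 2·F·n_NADH`, and the specific
  production rate in µmol h⁻¹ cm⁻² (`regen_metrics` and friends).
* **Synthetic ground truth.** Seeded generators for every input — including
  a finite-difference simulator of irreversible cyclic voltammetry
  (backward-Euler stepping of the 1-D diffusion problem with a
  Butler–Volmer flux boundary, `simulate_irreversible_cv`) and an
  internally consistent full-experiment generator (`make_bundle`) — so the
  entire pipeline can be validated against known truth without laboratory
  data.

## Worked example

Generate a noiseless synthetic regeneration experiment whose built-in truth
is 95 % selectivity and 80 % Faraday efficiency, then analyse it:

```r
library(nadhreg)
bundle <- make_bundle(list(selectivity = 0.95, eta_f = 0.80), seed = 1)
report <- run_analysis(bundle)
report
#> <run_report>
#>   cathodic peak: E_p = -1.0980 V, i_p = -4.520e-06 A
#>   Q_total = 0.9649 C, c(1,4-NADH) = 0.2 mM
#>   selectivity = 0.950, eta_F = 0.800, rate = 2 umol/h/cm2
#>   notice: no impedance spectrum attached
```

The analysis recovers the configured truth exactly: a 0.2 mM active-NADH
assay, a cathodic NAD⁺-reduction peak near −1.1 V, 0.9649 C of passed
charge (of which 80 % went into the 2-electron reduction), and a rate of
2 µmol h⁻¹ cm⁻² over the 4 cm² plate electrode in 1800 s.

Kinetics from simulated voltammograms at six scan rates:

```r
nus <- c(0.025, 0.05, 0.1, 0.2, 0.4, 1)
pts <- do.call(rbind, lapply(nus, function(nu) {
  sim <- simulate_irreversible_cv(cv_truth(), scan_rate = nu)
  pk <- detect_peaks(segment_sweeps(sim$cv)[[1]],
                     search_window = c(-1.4, -0.8))[[1]]
  data.frame(nu = nu, E_p = pk$E_p)
}))
peak_shift_fit(pts)
#> <kinetics_fit> slope = -59.2 mV/decade (n = 6, T = 293 K)
#>   alpha*n = 0.491
```

The simulator was configured with αn = 0.49; the full
detection-plus-regression chain recovers 0.491. An effective capacitance
from CPE parameters:

```r
effective_capacitance(1e-5, 1e4, 0.8)
#> [1] 5.348184e-06
```

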