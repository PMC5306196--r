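---
title: "Methods: the four-equilibrium surface model and how pcion fits it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the four-equilibrium surface model and how pcion fits it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcion)
```

## The model

A phosphatidylcholine (PC) membrane in a 1:1 alkali chloride exposes two
ionizable moieties per lipid: the phosphate `A⁻` and the trimethylammonium
`B⁺`. Four simultaneous association equilibria — `A⁻` with H⁺ and with the
alkali cation Me⁺, `B⁺` with OH⁻ and with Cl⁻ — together with the two mass
balances

$$a_{A^-} + a_{AH} + a_{AMe} = C_{PC}, \qquad
  a_{B^+} + a_{BOH} + a_{BCl} = C_{PC},$$

determine all six surface site concentrations in closed form. The net
surface charge density is $\sigma = F\,(a_{B^+} - a_{A^-})$, i.e.

$$\frac{\sigma(\mathrm{pH})}{F} =
  \frac{C_{PC}}{1 + K_{BOH}\,a_{OH} + K_{BCl}\,a_{Cl}} -
  \frac{C_{PC}}{1 + K_{AH}\,a_{H} + K_{AMe}\,a_{Me}}.$$

Every quantity is SI: surface concentrations in mol/m², bulk ion
concentrations in mol/m³, the four constants in m³/mol. `C_PC` is fixed by
the area one PC molecule occupies in the outer leaflet,
$C_{PC} = 1/(N_A \cdot \text{area})$; the default 65 Å² gives
2.555 µmol/m².

Assumptions worth keeping in mind:

* **Activities are concentrations.** No activity-coefficient model is
  applied, at 0.155 mol/l a deliberate simplification.
* **Bulk compositions are pH-independent.** `a_Me = a_Cl = c_salt`
  throughout a titration; the acid/base added to move pH is treated as
  negligible. `Kw` is fixed at 1e-8 (mol/m³)² and not coupled to
  temperature.
* **No electrostatic feedback.** Interfacial ion concentrations are not
  Boltzmann-enhanced by the surface potential; the model is a pure
  site-binding isotherm. A full Gouy–Chapman coupling is out of scope.
* **pH is on the molar concentration scale**, `a_H = 1000·10^(−pH)`
  mol/m³.

Because the positive branch of $\sigma$ shrinks and the negative branch
grows monotonically with pH, $\sigma$ is strictly decreasing whenever all
four constants are positive, so the isoelectric point (IEP) is unique.
Setting the two branch denominators equal and substituting
$a_{OH} = K_w/a_H$ yields

$$K_{AH}\,a_H^2 + (K_{AMe} a_{Me} - K_{BCl} a_{Cl})\,a_H - K_{BOH} K_w = 0,$$

whose positive root (computed with the cancellation-safe quadratic form,
or the linear solution when $K_{AH}=0$) is converted back to pH and
verified by a sign change of the model curve. With all constants zero the
curve is identically zero and a no-IEP error is raised rather than an
arbitrary pH.

## Electrokinetics

Microelectrophoresis measures the mobility $u$; charge density follows
from $\sigma = \eta u/d$ with the diffuse-layer thickness
$d = \sqrt{\varepsilon\varepsilon_0 R T/(2F^2 I)}$ (0.77 nm at
155 mol/m³, 25 °C). This simple proportional conversion is adopted exactly
as the experimental convention for this assay; Henry/Ohshima size
corrections and zeta-potential theory are out of scope. The ionic strength
defaults to `c_salt` alone — the H⁺/OH⁻ contribution is at most ~6 % at
pH 2 for a 0.155 M electrolyte — and `ionic_strength_with_hoh()` computes
the inclusive value for anyone who wants it. Physical defaults the assay
description leaves implicit are standard water at 25 °C: T = 298.15 K,
η = 8.90e-4 Pa·s, ε_r = 78.5; all overridable in `electrolyte_spec()`.

## Fitting

### Linearized route

At high proton concentration the model collapses to a line in the
transformed variables $y = \sigma a_H/F$, $x = a_H$:

$$y = \underbrace{\frac{C_{PC}}{1+K_{BCl}a_{Cl}}}_{\text{slope}}\; x
  \;-\; \underbrace{\left[\frac{C_{PC}K_{BOH}K_w}{(1+K_{BCl}a_{Cl})^2}
  + \frac{C_{PC}}{K_{AH}}\right]}_{-\text{intercept}},$$

and at low proton concentration, in $y' = \sigma/(F a_H)$ versus
$x' = 1/a_H$, to a line with slope $-C_{PC}/(1+K_{AMe}a_{Me})$ and
intercept $C_{PC}/(K_{BOH}K_w) + C_{PC}K_{AH}/(1+K_{AMe}a_{Me})^2$.
Ordinary least squares over a pH window gives the four coefficients; the
two slopes invert directly to `K_BCl` and `K_AMe`.

The two intercepts couple `K_AH` and `K_BOH`. Eliminating `K_AH` leaves a
quadratic in `K_BOH` which generically has **two positive roots, and both
reproduce the intercepts exactly**: the linearized coefficients alone do
not identify the pair. `constants_from_coefficients()` returns the root
closer (in log distance) to the dominant-term approximation
`K_AH ≈ C_PC/(−intercept_high)`, `K_BOH ≈ C_PC/(K_w·intercept_low)` and
attaches the other as an attribute; `fit_linearized()` then keeps
whichever root better explains the data outside the windows. It is
suggestive that the two roots are typically separated by many orders of
magnitude in `K_BOH` — the same qualitative split seen between published
per-salt values of this constant.

Three practical caveats, all of which the test suite exercises:

* The lines are **asymptotes**. Their validity needs
  $K_{AH}a_H \gg 1 + K_{AMe}a_{Me}$ and
  $K_{BOH}a_{OH} \ll 1 + K_{BCl}a_{Cl}$ (acid side; mirrored on the
  alkaline side). For realistic constants the default liposome windows
  (pH 2–4 and 7–8.5) sit only partially inside the asymptotic regime, and
  the truncation bias on the recovered constants can reach tens of
  percent; the bias shrinks steadily as the windows move toward the pH
  extremes. For LiCl-like constants the low-pH condition for the alkaline
  line fails everywhere below the pH 8.5 cutoff, and the regression slope
  comes out with the wrong sign — the fit then raises a
  model-inconsistency error instead of returning numbers.
* The **low-pH intercept is noise-fragile**: the $1/a_H$ transform
  amplifies alkaline-side scatter by orders of magnitude, and the
  intercept flips sign at noise levels far below the experimental one.
* Slope ratios implying a slightly negative constant
  (`C_PC/slope − 1 < 0` within 1e-9 relative) are clipped to zero with a
  recorded warning; larger violations are errors.

For all these reasons the linearized route is retained as a fast
diagnostic and as a starting point, while `fit_direct()` is the default
estimator.

### Direct nonlinear route

`fit_direct()` minimizes the (optionally inverse-variance weighted) sum of
squared charge-density residuals over $\log_{10}$ of the four constants,
bounded to [1e-8, 1e12] m³/mol — the constants span ten orders of
magnitude across salts, so the log parameterization is essential. The
search is multistart: 16 log-uniform random starts (seeded, hence
deterministic), plus the linearized estimate when it is computable, each
refined by bounded L-BFGS-B, with a final Levenberg–Marquardt polish of
the best candidate. Two safeguards address failure modes observed during
development:

* **Unweighted pre-fit.** With strongly unequal weights (replicate SDs
  proportional to $|\sigma|$ make near-IEP points enormously heavy) the
  weighted surface develops a spurious basin in which one binding branch
  is switched off entirely; an unweighted pre-fit supplies a robust extra
  start.
* **Bound-retry.** A solution pinned to a log bound is the signature of
  that spurious basin; up to three fresh multistart batches are run before
  such a solution is accepted.

Weights are `1/sd_sigma²` when every point carries a replicate SD,
otherwise unit. The condition number of the residual Jacobian (numeric,
central differences in log space) is reported, and fits with
κ > 1e8 — or a flat, identically zero curve, which leaves the constants
undetermined — are flagged non-identifiable.

### Uncertainty

`bootstrap_uncertainty()` is a residual bootstrap: residuals are
standardized by the fit weights, resampled with replacement, rescaled to
each point's own noise level, added back to the fitted curve, and the fit
is repeated (one Levenberg–Marquardt run from the point estimate) 200
times by default; 2.5/97.5 percentile intervals are reported per constant.
Standardizing before resampling is what keeps the scheme honest under
heteroskedastic replicate noise; with unit weights it reduces to the plain
residual bootstrap. Refit failures above 20 % of replicates mark the
result unreliable. In repeated-simulation checks at the experimental noise
level the intervals cover the generating `K_AMe` at roughly their nominal
rate (~91 % observed for the 95 % interval over 200 simulations).

## The synthetic generator

`generate_titration()` emulates the structure of the microelectrophoresis
experiment: a pH 2–10.5 grid, a 0.155 mol/l 1:1 alkali chloride, and for
each grid point `n_replicates` (default 6) Gaussian mobility draws around
the model value, stored as the replicate mean, the derived charge density,
the SD of the mean on the charge scale, and the count. Noise is applied to
the **mobility**, the quantity the instrument measures, and propagates to
σ through the linear conversion. The default per-replicate SD of 4.3e-9
m²/V/s makes the charge scatter ≈ 2 % of the full scale $F\,C_{PC}$ — a
stated assumption standing in for error bars the assay description does
not quantify. An optional artifact multiplies the true charge by
`exp(−rate·(pH − threshold))` above a threshold (default off), mimicking
the membrane breakdown that makes alkaline points untrustworthy; it exists
to exercise the pH ≤ 8.5 cutoff rule (`apply_window()`), not as membrane
chemistry. All draws come from a single seeded stream in fixed grid order,
so datasets are bit-reproducible.

What the generator does **not** emulate: liposome size distributions and
their electrokinetic consequences, pH-meter drift, buffer equilibria
(the experiment deliberately avoids buffers), inter-batch variability, or
any correlation between replicates. Passing round-trip tests therefore
demonstrates correctness of the estimation machinery under the model's own
noise structure — not robustness to every artifact of real titrations.

## Numerical choices

* Quadratics (IEP, intercept inversion) use the cancellation-safe root
  form and Vieta's relation for the companion root.
* The site-concentration closed forms agree with a generic
  row-equilibrated 6×6 linear solve of the equilibrium system to 1e-10
  relative for sites holding more than ~1e-5 of `C_PC`; below that,
  double-precision elimination cannot resolve componentwise relative error
  (the error floor is ε/f for occupancy fraction f), while the charge
  density itself agrees to ~1e-16 of full scale.
* Monotonicity of σ(pH) is exact up to floating-point plateaus in the
  saturated tails.
* Titration CSVs print 17 significant digits, so write/read round trips
  are value-exact.
* Test problem sizes: noiseless round trips use a 131-point pH 2–8.5 grid
  (step 0.05); stochastic checks use a 66-point grid (step 0.1) with 100
  noise seeds, and 50 outer repeats of a 200-replicate bootstrap.

## Known limitations

* The model IEP follows from the fitted constants; for LiCl-like constants
  it sits near pH 8.8, noticeably above the ~8.2 seen experimentally for
  that system — the package reports the model value and leaves the
  discrepancy to the user.
* `K_AH` and `K_BOH` are intrinsically weakly identified from a single
  titration at realistic noise (they shape only the curve's flanks);
  expect wide bootstrap intervals for them, and consider denser sampling
  of the acid flank when designing experiments.
* One salt at a time: no joint fitting across electrolytes with shared
  `K_AH`/`K_BOH`, no multi-salt mixtures, no di-/trivalent ions, no
  temperature dependence of the constants.
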