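---
title: "Predicting fat-free mass in preschool children from bioimpedance spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fat-free mass in preschool children from bioimpedance spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisffm)
library(dplyr)
```

## The measurement problem

Body composition in 2–5 year olds is hard to measure well: reference methods
such as dual-energy X-ray absorptiometry (DXA) require the child to lie still,
and field settings need something faster. Bioelectrical impedance is the usual
candidate. A small alternating current is passed through the body; its
opposition (impedance) reflects the conductive body water, and body water in
turn tracks fat-free mass (FFM). Two routes lead from impedance to FFM:

1. **Empirical prediction equations** — a population-specific regression of
   reference FFM on anthropometry and the *impedance index*
   \(L^2/R_{50}\) (height² over the 50 kHz resistance, cm²/Ω).
2. **Mixture theory** — a biophysical model converting the Cole-model
   resistances into extracellular (ECW), intracellular (ICW) and total body
   water (TBW), then dividing TBW by the hydration fraction of FFM.

`bisffm` implements both routes end to end, the pipeline that develops and
validates such equations (stratified splits, stepwise selection), the
method-agreement battery used to judge them, and a calibrated synthetic cohort
generator so everything can be exercised, tested and benchmarked without
subject-level data.

## The Cole model

Tissue impedance over frequency follows the four-parameter Cole model
\[
Z(f) = R_\infty + \frac{R_0 - R_\infty}{1 + (j f/f_c)^{1-\alpha}},
\]
a depressed semicircle in the resistance–reactance plane. \(R_0\) is the
zero-frequency resistance (current confined to extracellular water),
\(R_\infty\) the infinite-frequency resistance (all body water conducts),
\(f_c\) the frequency of maximal capacitive reactance, and \(\alpha \in [0,1)\)
a dispersion-broadening exponent. We use the \(f/f_c\) parameterisation rather
than \(\omega\tau\) — the two are equivalent and this one avoids unit
juggling. A cable time-delay correction is available as an argument
(`td_us`) but defaults to off; it is not part of the core model.

`fit_cole()` minimises the summed squared deviation jointly over the real and
imaginary parts with equal weights (the orthogonal misfit on the Cole plot),
via Levenberg–Marquardt. Starting values come from the data: \(R_0\) from the
largest measured resistance (×1.05), \(R_\infty\) from the smallest (×0.95),
\(f_c\) from the frequency of peak reactance, \(\alpha = 0.1\). On
semicircular loci this initialisation is robust; the noiseless round trip
recovers all four parameters to well below 0.1%. Reactance is stored
throughout as the **positive magnitude** of the capacitive reactance, removing
a sign-convention ambiguity between instrument export dialects.

Two derived quantities feed everything downstream: \(R_{50}\), the modelled
resistance at 50 kHz (the frequency single-frequency devices use), and
\(Z_c\), the impedance modulus at \(f_c\). Replicate fits are combined by the
parameter-wise median — robust to a single bad replicate and neutral among the
three — and the between-replicate CV of \(R_{50}\) is reported as a precision
summary. Fits whose RMS misfit exceeds 1% of \(R_0\) are flagged
(`quality_flag`), operationalising the practice of remeasuring poorly fitted
Cole plots; the threshold is an argument.

Degenerate spectra (zero reactance everywhere, or constant resistance) make
the model non-identifiable and raise a typed error rather than returning
nonsense.

## Mixture theory

Modelling the body as a conductor of length \(H\) whose conducting phase is
the ECW, with cells as non-conducting inclusions, Hanai's correction gives

\[
V_{ECW} = k_{ECW}\left(\frac{H^2\sqrt{W}}{R_0}\right)^{2/3},
\qquad
k_{ECW} = \frac{(K_b\,\rho_{ECW})^{2/3}}{100\,D_b^{1/3}},
\]

with height in cm, weight in kg, resistivity \(\rho_{ECW}\) in Ω·cm, body
density \(D_b\) in kg/L and the dimensionless body-geometry factor \(K_b\)
(default 4.3). With the De Lorenzo constants this yields \(k_{ECW} \approx
0.307\) and, for a typical 3.5-year-old, ECW around 4.2 L — about 27% of body
weight, as expected at this age. Note the \(K_b^{2/3}\) dependence: the
coefficient follows from the cylinder-conductor derivation, and the package's
tests pin it with an independent high-precision oracle.

ICW comes from the implicit equation
\[
\left(1 + \frac{V_I}{V_E}\right)^{5/2}
 = \frac{R_0 + R_I}{R_I}\left(1 + K_\rho \frac{V_I}{V_E}\right),
\qquad R_I = \frac{R_0 R_\infty}{R_0 - R_\infty},
\]
with \(K_\rho = \rho_{TBW}/\rho_{ECW}\) (≈ 104.3/40.5 = 2.58 for the
Hydra constants). The residual is monotone on the bracket, so the root is
found by bisection-safe root finding to 1e−12 followed by one Newton polish;
every returned root satisfies the defining equation to better than ten
significant digits.

Two numerical artifacts of this equation are worth knowing. First, FFM is
*not* monotone in \(R_0\) alone: raising \(R_0\) with \(R_\infty\) fixed
lowers \(R_I\), which raises ICW, and the two effects can trade places. The
physically meaningful monotonicity — scaling both resistances up (less water)
strictly lowers FFM — holds for every scheme and is what the tests assert.
Second, in the degenerate limit \(R_\infty \to R_0\) (no intracellular
conduction) the zero root of the implicit equation is repelling whenever
\(K_\rho > 2.5\), so ICW tends to a small structural value (≈ 4% of ECW for
the Hydra constants) rather than exactly zero. Neither regime occurs in real
pediatric spectra, but both are documented and tested so the behaviour at the
boundary is not a surprise.

The Moissl variant replaces the fixed coefficients with BMI-adjusted ones,
\(ECW = (a/\mathrm{BMI} + b)(H^2\sqrt W/R_0)^{2/3}\) and
\(ICW = (c/\mathrm{BMI} + d)(H^2\sqrt W/R_I)^{2/3}\) with the published
\(a = 0.188, b = 0.2883, c = 5.8758, d = 0.4194\). The ICW term uses the
intracellular resistance \(R_I\); with these inputs the Moissl chain gives a
TBW near 9.2 L for a child at the cohort's male covariate means — a hydration of roughly 77% of FFM,
squarely physiological.

FFM is then TBW divided by an age- and sex-specific hydration fraction (water
density 1 kg/L). The default table carries a single 3–4 y band (M 0.767,
F 0.776, nominal preschool values); multi-band tables keyed by
`age_min_days`/`age_max_days` are honoured per child, and a missing entry is a
configuration error, not a silent NA.

**The coefficient registry.** Six schemes are compared in the package:
the SFB7 device default, the same with personalised \(K_b\), Moissl, Xitron
Hydra, the original Xitron 4000B, and the 4000B with pediatric adjustments.
Only the De Lorenzo/Hydra constants and the Moissl coefficients are published;
device-firmware constants are not, so those registry rows are explicit,
documented stand-ins (`provenance` column) and every constant is overridable
via `mixture_config()`. The personalised-\(K_b\) scheme takes a per-child
`kb_personal` column and falls back to 4.3; estimating \(K_b\) from
anthropometric girths is out of scope. Conclusions about *ranking* the
firmware schemes therefore depend on assumed constants; conclusions about the
machinery (conservation, monotonicity, the published schemes) do not.

## The equation catalogue and its pipeline

All printed prediction equations are addressable by id in `ffm_equations()`:
the seven-model derivation ladder (weight alone through the final
weight + index + sex + ethnicity model), and the two previously published
preschool equations (Ejlerskov, gram scale; Rush, kg scale). "Length" and
"standing height" denote the same measured quantity at this age. Ethnicity is
the Asian/non-Asian indicator (Chinese and South Asian coded 1; White
Caucasian and Other coded 0). Evaluation is exactly affine — finite
differences reproduce the printed coefficients to machine precision — and
out-of-range anthropometry (weight outside 5–40 kg, height outside 70–130 cm)
warns rather than errors: the equations are documented as valid only near
their development cohort.

Fat mass is derived as weight minus predicted FFM, with two conventions:
the *adjusted* scale weight \(W_{adj} = 0.41 + 0.99\,W_{scale}\) (used for the
cohort's own equations and Ejlerskov) or the raw scale weight (Rush). The
printed adjustment is implemented as-is even though it slightly exceeds the
scale weight over the cohort's range; `develop_weight_adjustment()` refits the
mapping on any paired sample. Negative fat mass is returned but flagged.

The development pipeline mirrors the study design: a sex-stratified random
split (`round(fraction × stratum size)` derivation children per sex,
deterministic given the mandatory seed), OLS fitting with adjusted \(R^2\),
residual standard error (denominator \(n - p - 1\); the package's "RMSE"),
and standardized coefficients \(b_j\,SD(x_j)/SD(y)\). Stepwise selection is
bidirectional on AIC — the conventional implementation of "bi-directional
stepwise" where the criterion is otherwise unspecified; meal/void-type
categorical covariates would enter as ordinal integers. Rank-deficient
designs name the collinear terms in the error.

## The agreement battery

Throughout, differences are **predicted − reference**, so a positive bias is
overestimation; this convention is applied uniformly. The battery in
`agreement()` comprises:

* **MAPE**, \(100/n \sum |p_i - r_i|/r_i\);
* **Pearson r** and **Lin's CCC**
  \(2 s_{xy}/(s_x^2 + s_y^2 + (\bar x - \bar y)^2)\), with the CI from the
  Fisher z-transform and Lin's asymptotic variance (no CI method is canonical
  here; Fisher z is the standard choice). CCC uses moment (1/n) estimators,
  so \(|CCC| \le |r|\) exactly;
* **Bland–Altman**: bias, SD of differences (n−1 denominator), limits of
  agreement bias ± 1.96 SD (an exact identity in every report), and a
  proportional-bias p-value from the t-test of the slope of differences on
  pairwise means — the natural test for a trend visible in a Bland–Altman
  plot;
* **Passing–Bablok**: slope = the K-shifted median of all pairwise slopes
  (pairs with tied x discarded; slopes of exactly −1 discarded; K = number of
  slopes below −1), intercept = median(y − slope·x), rank-based CIs. With an
  even slope count the two middle order statistics are averaged
  arithmetically. The −1 offset buys axis-swap symmetry; it also means exact
  scale equivariance holds only when no slopes straddle −1 — always the case
  in method comparison of two positively correlated measures;
* **TOST equivalence**: two one-sided paired t-tests against ±bound
  (0.25 kg for FFM, 0.10 kg for FM), p = the larger one-sided p, and the
  decision provably identical to the 90% CI of the mean difference lying
  inside the bounds. Zero-variance differences are decided exactly.

## The synthetic cohort: what it emulates, and what it does not

The generator (`generate_cohort()`) reproduces the *statistical structure* the
analysis assumes, not pediatric physiology at large:

* sex ~ Bernoulli(25/65), Asian ethnicity ~ Bernoulli(14/65);
* height normal within sex (M 100.3 ± 3.4 cm, F 98.6 ± 3.5 cm); weight affine
  in height plus noise, matching the within-sex weight distributions
  (M 15.7 ± 2.0 kg, F 15.3 ± 1.7 kg) and a weight–height correlation of 0.6;
* latent true FFM affine in weight, sex and ethnicity plus a physiological
  residual of SD 1.06 kg, calibrated so sex-specific FFM means are
  M 12.0 / F 11.1 kg with an Asian-ethnicity effect of 0.28 kg;
* the impedance index obtained by **inverting the final impedance equation**
  at the latent FFM, whence \(R_{50} = H^2/\text{index}\); \(R_0\) and
  \(R_\infty\) follow from the ratios 1.090 and 0.828 (treated as
  sex-invariant), and \(f_c\) is solved in closed form so the modelled 50 kHz
  resistance equals \(R_{50}\) (a quadratic in \((50/f_c)^{1-\alpha}\));
* triplicate 256-point spectra (3–1000 kHz, logarithmic) with a
  replicate-level multiplicative gain of CV 0.17% plus equal per-frequency
  noise. The gain term matters: iid per-point noise alone would average out
  over a 256-frequency fit and could not produce a 0.17% between-replicate CV
  of the fitted \(R_{50}\);
* DXA FFM = latent FFM + N(0, 0.39 kg); DXA weight on the adjusted-weight
  line plus N(0, 0.05 kg); DXA FM = DXA weight − DXA FFM;
* age ~ N(1232, 60) days, feeding only the hydration lookup.

Defining truth through the final equation is deliberate: it gives the
development pipeline a known ground truth, so parameter recovery, the ladder
ordering and the validation error are properties the simulation can actually
certify. The price is circularity with respect to the equation itself — the
simulation can show that the pipeline *recovers* the model under the stated
noise, not that the model is *true* of children. Likewise the published
Ejlerskov and Rush equations are evaluated against this NiPPeR-anchored truth,
which is exactly how their biases arise in the validation study.

Two generator constants are free calibration choices, set once. The
conditional FFM~weight slope (0.15 kg/kg) and the 1.06 kg residual jointly fix
the pooled FFM dispersion near 1.18 kg — the level implied by the reported
residual error (0.39 kg) and explained variance (88%) of the final model; a
steeper slope would push the simulated explained variance above 91%. Both are
`synth_config()` fields. One consequence to keep in mind: only the *final
impedance model's* error structure is anchored. Because the physiological
residual dominates and is invisible to height and weight, the intermediate
anthropometric ladder rows explain far less variance in simulation than their
real-data counterparts; the ladder's qualitative ordering (the impedance index
beats height as weight's partner) is preserved and tested, the intermediate
\(R^2\) magnitudes are not. Children whose derived \(R_{50}\) leaves (300,
1500) Ω are redrawn within their own RNG stream (streams are keyed by seed and
child index, so a child's draw survives reordering); redraws are counted and
capped.

What passing tests show, and what they do not: the suite certifies the
numerical machinery and the statistical pipeline under this generative model.
It does not certify electrode placement effects, DXA movement artifact,
hydration departures in illness, or any population beyond the emulated
covariate ranges.

## Problem sizes and reproducibility

The validation summaries are computed at the study's own scales: derivation
n = 45, validation n = 20, whole cohort n = 65, averaged over 200 independent
seeds; generator calibration checks use n = 10,000. `scripts/acceptance.R`
recomputes all headline quantities from scratch at these sizes from a single
seed. `run_pipeline()` threads one seed through simulation, split, fitting and
validation, embeds it and a configuration hash in its outputs, and re-running
with the same seed reproduces every file byte for byte.

## A worked run

```{r pipeline}
run <- run_pipeline(seed = 1)
run

select(run$ladder, equation, adj_r2, rmse_kg)

select(run$comparison, method, mape_pct, ccc, bias_kg, loa_low_kg,
       loa_high_kg)
```

The Bland–Altman view of any report:

```{r ba-plot, fig.width = 6, fig.height = 4}
autoplot(run$validation$impedance$ffm)
```

## Known limitations

* Firmware constants for the SFB7 and Xitron 4000B schemes are assumed;
  their comparative rankings are illustrative until real constants are
  supplied through `mixture_config()`.
* The hydration defaults are nominal single-band values; serious use should
  supply a referenced multi-band table.
* The generator's resistance ratios are sex-invariant and its FFM truth is
  equation-anchored (see above).
* Nonparametric limits of agreement, segmental impedance modelling and
  skinfold-augmented models are out of scope.
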