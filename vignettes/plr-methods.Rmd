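---
title: "Methods: waveform model, light correction and the PuRe score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform model, light correction and the PuRe score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling choices behind **purescore**: the
canonical waveform, the definition of each extracted parameter, the
ambient-light correction machinery, the PuRe score and its clinical
rescaling, the synthetic cohort generator, and the numerical decisions
that were open to interpretation. Every empirical claim made here is one
the package's test suite or `scripts/acceptance.R` actually computes; no
additional results are asserted.

## 1. The canonical waveform

A pupillogram around a flash stimulus is modelled as the sum of two
logistic sigmoids on a baseline:

$$D(t) = b - a_1\,\sigma\!\left(\frac{t - t_1}{s_1}\right)
           + a_2\,\sigma\!\left(\frac{t - t_2}{s_2}\right),
  \qquad \sigma(x) = \frac{1}{1 + e^{-x}},$$

with $b$ the pre-flash asymptote (mm), $a_1, t_1, s_1$ the amplitude
(mm), midpoint (s) and time-scale (s) of the constriction phase, and
$a_2, t_2, s_2$ the same for re-dilation. Physiological constraints are
enforced throughout: $s_1, s_2 > 0$, $t_2 > t_1$, $0 \le a_2 \le a_1$,
$b > 0$ and $b - a_1 > 0$ (the pupil never closes). The limits are
$D(-\infty) = b$ and $D(+\infty) = b - a_1 + a_2$ (the FIN asymptote).
The analytic derivative has, for well-separated sigmoids, a minimum of
$\approx -a_1/(4 s_1)$ near $t_1$ and a maximum of $\approx a_2/(4 s_2)$
near $t_2$; velocities are read from this analytic derivative, not from
noisy finite differences of the samples.

### Fitting

`plr_fit()` minimises the residual sum of squares under the constraints
with `optim(method = "L-BFGS-B")` and an analytic gradient (verified
against finite differences in the test suite). The working
parameterisation is $(b, a_1, t_1, s_1, \Delta t, r, s_2)$ with
$t_2 = t_1 + \Delta t$ and $a_2 = r\,a_1$, $r \in [0, 1]$, which turns
the ordering and amplitude constraints into box bounds. The constraint
$b - a_1 > 0$ is kept soft via a quadratic penalty ($10^6 \cdot
\mathrm{gap}^2$ below a 0.05 mm margin) so the optimiser can traverse
the boundary. Initialisation uses a deterministic multistart grid
(three constriction midpoints, two time-scales) rather than random
restarts, so a fit is a pure function of its input — byte-reproducible
across runs and machines. Box bounds keep the midpoint within 1.5 s of
flash onset and the time-scales below 0.5 s / 1.5 s; without them,
near-flat recordings allow the latency parameter to wander arbitrarily.

## 2. Extracted parameters

`plr_parameters()` implements the standard definitions. Units: mm for
diameters, mm/s for velocities, s for times.

| Parameter | Definition |
|---|---|
| INIT | mean diameter over the initial 250 ms of the recording |
| END  | median of the raw samples in a 130 ms window centred on the post-flash minimum, searched within 1.5 s after flash onset |
| FIN  | fitted asymptote $b - a_1 + a_2$ |
| CAMP | INIT − END |
| MCV  | minimum of the analytic derivative on the constriction phase (signed, ≤ 0) |
| PDV  | maximum of the analytic derivative after the trough (≥ 0) |
| LAT  | $(t_1 - s_1 \ln 99) -$ flash onset |
| T75  | first time after the model trough at which $D(t) \ge \mathrm{END} + 0.75\,\mathrm{CAMP}$, minus the trough time |

Two definitions needed a concrete numerical choice:

* **LAT** — "commencement of constriction" is taken as the time at
  which the constriction sigmoid has completed 1% of its excursion,
  i.e. $\sigma = 0.01$, giving the closed form $t_1 - s_1\ln 99$.
  The 1% level is a threshold on the *model*, so latency is immune to
  sample noise; a different small threshold would shift LAT by a
  constant multiple of $s_1$ and be absorbed by the light correction.
* **END** — computed from raw samples (not the fit) as a median over a
  130 ms window *centred* on the sample minimum, clipped to the
  recording; this makes END robust to single-sample outliers while
  staying faithful to the data. If no trough is found within 1.5 s the
  recording is flagged non-constricting and END = INIT, CAMP = 0.
* **T75** — measured on the fitted curve; if the asymptote FIN never
  reaches END + 0.75 CAMP the parameter is flagged unreached and the
  recording's recovery time is reported as the censoring value.

## 3. Ambient-light correction

Every raw parameter depends on ambient light through two observable
proxies: the baseline diameter $B$ (INIT) and the camera exposure $E$.
For each parameter (all except INIT, which *is* the baseline proxy),
`fit_plr_corrections()`:

1. builds the 12-term feature library
   $B,\ E,\ B^2,\ E^2,\ B^{-1},\ E^{-1},\ \log B,\ \log E,\
   (\log B)^2,\ (\log E)^2,\ B\!\cdot\!E,\ \log B \cdot \log E$;
2. ranks subsets by BIC, $n\ln(\mathrm{RSS}/n) + k\ln n$, using a
   forward–backward stepwise search with a visit registry; when the
   term pool has at most 8 terms the search is replaced by exhaustive
   enumeration (256 subsets), and the test suite checks that on a
   4-term pool the stepwise ranking equals the brute-force one;
3. refits each short-listed candidate with a LASSO penalty at the fixed
   regularisation weight α = 0.006 (via `glmnet`; closed-form
   soft-thresholding for single-term models, OLS for α = 0);
4. picks the winner by leave-one-*subject*-out cross-validated MSE, so
   model choice is never driven by within-subject correlation.

The corrected value is

$$\text{corrected} = \overline{\text{cohort}} + \text{measured} - \text{predicted},$$

which has the exact identity (unit-tested): if measured equals
predicted, the corrected value is the cohort average. For scoring new
subjects the package also offers `correct_plr_loso()`, which corrects
each subject using models trained only on the remaining subjects.

The residual illumination effect is quantified by `light_anova()`: a
repeated-measures F statistic comparing `values ~ subject +
illumination` against `values ~ subject`. The acceptance suite requires
F(corrected) < F(raw) for all seven corrected parameters on the
synthetic lighting study and a ≥ 10× reduction for CAMP.

## 4. The PuRe score

The shipped `pure_model()` combines INIT and the corrected parameters
linearly:

$$\text{PuRe}_{\text{raw}} = 0.007\,\text{INIT} - 2.438\,\text{END}_c
  + 2.773\,\text{FIN}_c + 0.838\,\text{MCV}_c + 1.239\,\text{PDV}_c
  + 2.604\,\text{CAMP}_c.$$

`fit_pure_scaler()` maps raw scores onto the clinical 0–5 scale with a
piecewise-linear function anchored at seven points derived from a
reactive ("pre") and an unreactive ("post") calibration sample
($m$ = median, $s$ = sample standard deviation):

| raw | $m_{\text{post}}\!-\!3s$ | $m_{\text{post}}\!-\!s$ | $m_{\text{post}}$ | $m_{\text{post}}\!+\!s$ | $0$ | $m_{\text{pre}}\!-\!3s_{\text{pre}}$ | $m_{\text{pre}}$ |
|---|---|---|---|---|---|---|---|
| scaled | −0.5 | 0.2 | 0.8 | 1.0 | 3.0 | 4.0 | 4.5 |

Between anchors the map interpolates linearly; beyond the outermost
anchors it extrapolates with the end segments' slopes; the result is
clamped to [0, 5]. Calibration requires the anchor sequence to be
strictly increasing (overlapping pre/post distributions are rejected)
and at least three scores per sample. Classes: 0 → non-reactive,
(0, 3] → abnormal, (3, 5] → normal.

`train_pure_model()` re-derives the linear weights from labelled data:
logistic loss + α‖β‖₁ + γ·V, where V is the variance across
illumination levels of the mean score of reactive recordings (a
quadratic form β′Qβ). The smooth part (logistic + invariance) is
minimised by FISTA with backtracking; the L1 part by soft thresholding;
with α = 0 plain BFGS is used instead and, as the tests verify, agrees
with `glm(..., family = binomial)`. Features are standardized
internally and coefficients reported on the original scale.

## 5. The synthetic generator

`simulate_*_study()` exist so the pipeline can be exercised end to end
with known ground truth. Realism choices:

* **Baseline vs. light** — a Hill curve
  $b(\ell) = d_{\min} + (d_{\max} - d_{\min})/(1 + (\ell/L_{1/2})^h)$
  with subject-level $d_{\max} \sim U(6.2, 7.8)$ mm,
  $d_{\min} \sim U(2.1, 2.9)$ mm, half-constriction point
  $L_{1/2} \sim \exp U(\log 30, \log 120)$ lx and slope
  $h \sim U(0.5, 0.9)$ — monotone light–pupil coupling with wide
  between-subject spread.
* **Exposure proxy** — $E(\ell) = E_{\max}/(1 + \ell/L_E)$ with 5%
  lognormal jitter, mimicking a camera's monotone-decreasing firmware
  exposure.
* **Kinetics under light** — amplitude $a_1$ scales with the distance
  of the baseline from $d_{\min}$; time-scales and midpoints shift
  linearly with baseline diameter, so *every* extracted parameter
  (including LAT and T75) carries a genuine illumination dependence for
  the correction to remove.
* **Mydriasis** — the drugged state pins the baseline near $d_{\max}$
  and multiplies the constriction amplitude by δ = 0.02, giving
  near-abolished, but not identically zero, responses.
* **Determinism** — every recording draws its noise from a substream
  seed derived by a polynomial hash of the master seed and the
  recording's labels, so studies are reproducible element-wise and
  insertion-order independent.

Limits, deliberately accepted: traces are generated *from* the
canonical model plus Gaussian noise, so fitting is well-specified by
construction — the generator validates the pipeline's statistics, not
the model's physiological adequacy; there are no blinks, gaze drift, or
asymmetric noise; exposure is a clean monotone proxy rather than a real
firmware log.

Default study designs: lighting — 9 subjects × 8 illumination levels
(5–10 000 lx) × 5 repeats = 360 recordings; mydriasis — 15 subjects ×
2 eyes × pre/post = 60 recordings at clinic lighting (12–120 lx).

## 6. Numerical choices at a glance

* BIC uses the Gaussian profile form $n\ln(\mathrm{RSS}/n) + k\ln n$
  with $k$ counting the intercept.
* `exhaustive_limit = 8`: exhaustive subset enumeration is exact and
  costs ≤ 256 OLS fits, so the stepwise heuristic is only used for
  larger pools.
* Stepwise selection requires ≥ 10 observations; LOSO correction
  requires ≥ 3 subjects.
* JSON model files carry 15 significant digits (round-trip error
  ~1e−15 relative); CSV tables carry 9 significant digits
  (~5e−9 relative) — both formats are covered by round-trip tests at
  matching tolerances.
* All fits, simulations and selections are deterministic given their
  seeds; the test suite includes a byte-identity check on the full
  pipeline's output files.

## 7. Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, against
the installed package: the score coefficients on unit inputs, the four
scaler anchor values after calibrating on synthetic
Normal(2, 0.5)/Normal(−2, 0.6) score samples, and the end-to-end
mydriasis classification accuracy (in %). The same quantities, plus the
structural properties listed above, are asserted by
`tests/testthat/`.
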