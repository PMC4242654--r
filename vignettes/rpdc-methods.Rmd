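---
title: "Renormalized partial directed coherence for EEG state contrasts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renormalized partial directed coherence for EEG state contrasts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpdc)
```

## The model and what it assumes

The package infers directed interactions among EEG channels from a vector
autoregressive (VAR) description of the multichannel signal. For $M$
channels,
$$x(t) = \sum_{r=1}^{p} a(r)\, x(t-r) + \varepsilon(t),$$
with $\varepsilon(t)$ zero-mean multivariate Gaussian white noise with
covariance $\Sigma$. The entry $a_{jk}(r)$ is the linear effect of channel
$k$, $r$ samples back, on channel $j$ now; channel $k$ Granger-causes
channel $j$ given all other channels when these entries are not all zero.
The assumptions that matter in practice are (i) approximate stationarity
within each analysis window — addressed by the sliding-window design, not by
time-varying estimation — (ii) stability of the fitted model (companion
spectral radius below one), which `fit_var()` always evaluates and the
pipeline gates on, and (iii) adequacy of the linear-Gaussian description,
which `residual_diagnostics()` probes through a multivariate portmanteau
(whiteness) test and per-channel omnibus moment (normality) tests.

In the frequency domain, with
$A(\omega) = \sum_r a(r) e^{-i\omega r}$, $\bar A = I - A$,
$H = \bar A^{-1}$, the spectral matrix is
$S(\omega) = H \Sigma H^\ast / 2\pi$. The $1/2\pi$ convention is chosen so
that the integral of $S$ over $[-\pi, \pi]$ equals the process covariance
exactly (tested against the analytic lag covariance); the renormalized
statistic below is unaffected by this constant.

Renormalized partial directed coherence forms, per ordered pair
$k \to j$, the vector
$Z_{jk}(\omega)$ of the real and imaginary parts of the coefficient
transform and its asymptotic covariance
$V_{jk}(\omega) = \Sigma_{jj}\, C(\omega) [R^{-1}]_{kk}\, C(\omega)'$,
where $R$ is the covariance of the stacked $p$-lag process, $[R^{-1}]_{kk}$
its source-channel lag block and $C(\omega)$ the matrix of
$\cos(\omega l)$ and $\sin(\omega l)$ lag weights. Then
$$\lambda_{jk}(\omega) = Z_{jk}' V_{jk}^{-1} Z_{jk} \ \ge 0 .$$
Under the null of no $k \to j$ coupling, $N\hat\lambda_{jk}(\omega)$ is
asymptotically $\chi^2_2$, giving the constant significance level
$\chi^2_{2,1-\alpha}/N$ — at $\alpha = 0.05$ and $N = 5400$ (one 60 s
window at 90 Hz), 0.0011 to two significant figures. Because the magnitude
of $\lambda$ is interpretable absolutely, strengths can be compared across
frequencies and channel pairs, which is what the state-contrast stage does.

Two conventions are fixed project-wide to prevent transposition bugs:
$\lambda_{jk}$ means *source $k$, target $j$* (matching $a_{jk}(r)$), and
every reported pair is written `SOURCE->TARGET`. Any sign-consistent choice
of the two components of $Z$ (from $A_{jk}$ or $\bar A_{jk} = -A_{jk}$)
yields the same $\lambda$; the implementation uses the
$(\sum_l a\cos, \sum_l a\sin)$ form together with the matching
$[\cos\cos, \cos\sin; \sin\cos, \sin\sin]$ weighting, which is internally
consistent. $\lambda$ is also exactly invariant under per-channel
rescaling (a similarity transform of the model), so the per-window variance
normalization does not bias it.

## The processing chain and its parameters

| parameter | default | units | rationale |
|---|---|---|---|
| analysis rate | 90 | Hz | keeps the VAR small enough for reliable estimation while covering the EEG bands of interest (Nyquist 45 Hz) |
| window / step | 60 / 5 | s | sliding-window stationarity compromise; 60 s at 90 Hz gives $N = 5400$ |
| model order $p$ | 22 | – | the production order for the 18-channel montage; small synthetic sets use smaller orders (the shipped state scenarios are VAR[4]; the package's own end-to-end profile fits $p = 6$) |
| $\alpha$ | 0.05 | – | conventional risk level; threshold $-2\ln\alpha/N$ |
| frequency grid | 0.5–45 by 0.25 | Hz | $\omega = 0$ excluded: the imaginary part of $Z$ vanishes there and $V$ becomes effectively rank one |
| exclusions | Cz | – | excluded from VAR fitting (not from the reference computation) |

**Hjorth re-referencing.** Each channel is re-expressed relative to the
mean of its spatial neighbors, accentuating local activity. The shipped
19-channel 10/20 neighbor table follows standard small-Laplacian practice
(e.g. O1: P3, T5; F3: Fp1, F7, C3, Fz) and is user-overridable; correctness
is tested against the operation's own definition (linearity, exact
neighbor-mean arithmetic), since no canonical published table exists for
this layout. Exclusion is applied *after* re-referencing: an excluded
channel still serves as a neighbor.

**Resampling.** 256 to 90 Hz is the rational factor 45/128, implemented as
polyphase FIR resampling with a Kaiser-windowed (beta 7.86, ~80 dB
stopband) low-pass at the narrower Nyquist limit and exact group-delay
compensation, i.e. zero phase overall — phase distortion in the resampler
would bias directed estimates. Edges are reflection-padded. Tests pin DC
preservation, sample-level phase accuracy on a sinusoid, and <2% energy
change for signals band-limited below 40 Hz. (The `signal` package's
`resample()` was not used because direct experiment showed a gain defect;
only its filter-design functions `fir1()`/`kaiser()` are used.)

**Normalization.** Windows are zero-meaned and divided by the per-channel
standard deviation in its population form (denominator $n$), making the
unit-variance invariant exact; at $N = 5400$ the difference from $n-1$ is
below 0.02%.

**Estimation.** Ordinary least squares on the lagged regression without
intercept (windows are zero-mean). The process covariance $R$ entering the
renormalization is the empirical moment matrix of the stacked lag
regressors — exactly the quantity whose inverse appears in the estimator's
asymptotic covariance; the analytic Yule–Walker/Lyapunov solution
(`yule_walker_covariance()`) is retained as an independent oracle and
agrees within 5% (Frobenius) at large $N$ in the tests. `fit_var()` reports
`sample_count` as the window's data-point count $n$ (the $N$ the constant
threshold is quoted at); the regression itself uses $n - p$ rows.

**Order selection.** The production choice of a single fixed order
reflects judgment (parametric-vs-nonparametric spectral comparison, fit
error, residual properties); `select_order()` makes the components explicit
— AIC, BIC, stability, portmanteau p, and a spectral-mismatch score (mean
squared log-ratio of the parametric spectrum against a segment-averaged
Hann-tapered periodogram) — and ranks deterministically by BIC with
unstable fits ineligible. It reports; it does not claim to reproduce a
manual choice.

## Numerical choices and degenerate inputs

- $V_{jk}(\omega)$ is a 2×2 system solved in closed form; when its
  determinant is negligible relative to $V_{cc}V_{ss}$ (relative tolerance
  $10^{-12}$, which occurs by symmetry as $\omega \to 0$ or $\pi$), a
  Moore–Penrose pseudo-inverse is used and a warning is logged with the
  count of affected cells.
- Unstable windows are recorded as missing cells in time-frequency maps,
  never interpolated; runs abort when more than half the windows are
  unstable, advising a smaller order.
- Zero-variance channels inside a window are an error naming the channel
  and window start (no silent dropping).
- A zero-condition-variance state matrix returns $F = 0$ by convention,
  covering the 0/0 case where the error stratum is also empty.
- Windows are half-open in time, $[\mathrm{start}, \mathrm{start} + 60)$,
  with sample index $\lfloor t \cdot \mathrm{rate} \rfloor$; the window
  count is $\lfloor(\mathrm{duration} - 60)/5\rfloor + 1$.
- All randomness flows from explicit integer seeds; identical
  (scenario, $n$, seed) triples give bit-identical simulations, and
  per-segment/per-subject seeds are derived deterministically.

## State epochs and the statistical stage

The four 30 s statistical epochs are derived from session markers: AWA
starts 2 min before infusion start; SED and LOC end 1 min before their
tests; "ROC: ending 1 min after ROC-testing" is genuinely ambiguous and is
read here as the epoch $[\mathrm{ROC}+30, \mathrm{ROC}+60)$ — a documented
convention, not a claim about intent.

A 30 s epoch clashes with the 60 s window at which the significance level
is quoted. The default policy (`epoch_mode = "sliding"`) reconciles them:
the state value is the mean of sliding-window rPDC over all 60 s windows
whose centers fall within 15 s of the epoch center (7 windows at the 5 s
step), keeping the quoted $N = 5400$ threshold; `epoch_mode = "single"`
fits one 30 s window ($N = 2700$) instead.

Band rPDC per subject × state × directed pair (arithmetic mean over grid
frequencies inside the band, edges inclusive) is log-transformed (natural
log; positivity is enforced) and analyzed by classical one-way
within-subject ANOVA: $SS$ decomposition into subjects, conditions and
error, $F = MS_{cond}/MS_{err}$ on $(k-1, (k-1)(n-1))$ df. No sphericity
correction is applied by default (Greenhouse–Geisser is available behind a
flag). Paired comparisons versus AWA use paired two-tailed t-tests on the
log values with Bonferroni correction $\min(1, m\,p)$, default $m = 3$;
the post-hoc machinery behind the reported structure is not uniquely
determined by it, and paired t-tests are the simplest procedure consistent
with a three-column AWA-referenced report — documented and configurable
rather than asserted.

## What the synthetic generator emulates — and what it does not

Scenarios are stable VAR processes with 10/20-labelled channels,
oscillatory (alpha-band) self-dynamics — AR(2) poles at radius 0.85–0.9 and
10 Hz — and directed couplings shaped by short band-tuned FIR tap sets so
that the influence concentrates in a stated band. The four `state_*`
scenarios share one 6-channel set (F3, F4, P3, P4, O1, O2: the pairs the
state analysis actually summarizes; the full 18-channel montage is still
supported by the pipeline) and differ only in coupling gains:

- **AWA**: back-to-front dominant — occipital→frontal coupling tuned to
  8–16 Hz; a weak parietal→frontal coupling that stays constant across all
  states acts as a designed null contrast.
- **SED / LOC**: occipital→frontal reduced to 25% / 20% of the AWA gain;
  frontal→occipital coupling tuned to 10–20 Hz appears (LOC strongest),
  plus frontal→parietal 1–12 Hz coupling at LOC.
- **ROC**: partial reversion — neither direction restored fully (35% of
  the AWA back-to-front gain, 30% of the LOC front-to-back gain).

Coupling gains (0.22 for the two principal directions) were calibrated
once by simulation so that designed-direction band rPDC clears the
$N = 5400$ threshold with power above 0.9 in a single 60 s window, then
frozen in the scenario library; no quantitative effect sizes exist to match
in the source setting, so magnitudes target detection power, not reported
means. The default session plays AWA→SED→LOC→ROC for 150 s each at 90 Hz,
with markers placed so each state's 30 s epoch sits at the center of its
segment — keeping the ±15 s window-center policy inside one state segment.

What the generator deliberately does *not* emulate: volume conduction or
any biophysical forward model, real-EEG artifacts (eye blinks, EMG, line
noise), non-stationarity within a state, heavy-tailed innovations, or
between-subject variation in coupling structure (subjects differ only by
innovation seed, which makes the synthetic between-subject dispersion far
smaller than clinical dispersion). Passing end-to-end tests therefore shows
that the chain recovers known directed couplings and their state contrasts
under its own model assumptions — not that it is robust to reference
choice, artifacts or model misspecification on real recordings. Simulated
scenarios generate locally referenced activity directly, so the synthetic
profile runs with `rereference = FALSE`; applying the Hjorth mixing to a
ground-truth VAR would scramble the designed couplings, and the
re-referencing operator is instead verified by its own unit and property
tests.

## Problem sizes used by the test suite

The suite favors many medium-size checks over few large ones: null
calibration aggregates 100 single-window fits at $N = 5400$;
direction recovery uses 100 seeds at one window each; oracle equivalence
fits at $N = 20000$; the end-to-end state-contrast run simulates ten
600 s sessions (four 150 s segments) at 90 Hz with a VAR[6] fit per
epoch window; ANOVA null calibration uses 1000 simulated 10×4 matrices and
the family-wise-error check 500. The full suite runs in well under a
minute of CPU.

## Known limitations

- The exact neighbor sets and resampling filter of any given lab are
  unpublished; results on real data are sensitive to both. The defaults
  here are standard practice, not reconstructions.
- rPDC inherits the usual caveats of VAR-based directed measures:
  sensitivity to unobserved common inputs, to reference choice, and to
  preprocessing that alters the correlation structure.
- No time-varying VAR estimation: temporal dynamics are resolved only at
  the sliding-window scale.
- The chi-square threshold is asymptotic; at $N = 5400$ the null
  exceedance rate measured in the tests is close to, but slightly above,
  the nominal 5% (finite-sample effect), which is why the calibration
  check uses an interval rather than a point.
- Original (non-renormalized) PDC, generalized PDC and DTF are not
  provided; no bootstrap or surrogate-based thresholds.
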