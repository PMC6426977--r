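---
title: "Dynamical stability of multichannel recordings: model, features, and classification"
author: "dynstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical stability of multichannel recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynstab)
```

## The model

The package treats a multichannel recording $y_n \in \mathbb{R}^N$ (ECoG-like
data: $N$ channels sampled at $S_f$ Hz, $dt = 1/S_f$) as *locally linear*: on a
short window of duration $\delta$, the dynamics are approximated by a
first-order vector autoregression,

$$ y_{n+1} = A\, y_n + u_n, $$

with $u_n$ white noise. `fit_var1()` estimates $A$ by minimum-norm least
squares over the window's sample-to-sample transitions (SVD pseudoinverse,
relative singular-value cutoff `rcond = 1e-10`). A window of $T$ samples gives
$T-1$ regression equations — at $\delta = 500$ ms and 1 kHz that is 500
samples and 499 transitions. An intercept is fitted by default as a nuisance
(it absorbs any nonzero window mean without biasing $A$; demeaning the window
and disabling the intercept is an equivalent path). Stability analysis uses
the eigenvalues of $A$ only.

Each eigenvalue $\lambda_j = \rho_j e^{i\varphi_j}$ of $A$ maps to a
*dynamical mode* with physical coordinates

$$ f_j = \frac{|\varphi_j|}{2\pi\,dt} \quad\text{(Hz)}, \qquad
   \tau_j = \frac{\log \rho_j}{dt} \quad\text{(1/s, natural log)}. $$

$\tau_j < 0$ is a damped mode, $\tau_j = 0$ marginal, $\tau_j > 0$ unstable.
The absolute value of the argument folds each conjugate pair onto one
nonnegative frequency; both members are kept, so conjugate pairs contribute
two identical $(f, \tau)$ points and all downstream histograms are uniformly
doubled in count but unchanged in shape. Eigenvalues exactly at zero
(nilpotent directions) have no finite timescale: they carry a $\tau = -\infty$
sentinel and are excluded from every binned distribution.

The scientific premise is that awake cortical dynamics hover near *marginal
stability* (many modes with $\tau \approx 0$, supporting long-range
interactions), whereas anesthesia *stabilizes* the dynamics (drives $\tau$
strongly negative). The pipeline turns that contrast into features, a
time-course diagnostic, and a single-trial classifier.

## DS vectors

For a segment of duration $\Delta \ge 0.5$ s, `make_ds_vectors()` samples the
mode distribution by fitting 10 equally spaced VAR(1) models on
$\delta = 0.5$ s sub-windows (`subwindow_starts()`; for $\Delta < 5$ s they
overlap, at $\Delta = 5$ s they tile exactly, and at $\Delta = 0.5$ s all ten
coincide — degenerate but permitted). The pooled modes are binned on a fixed
20 × 20 grid: $\tau \in [-250, 25]$ 1/s linear, $f \in [4, 256]$ Hz
logarithmic base 2 (`ds_grid()`). Bins are half-open $[\mathrm{lo},
\mathrm{hi})$ with the final bin closed; flattening is row-major over $\tau$
rows with frequency varying fastest, giving a length-400 count vector. Modes
outside the grid — including real modes at $f = 0$ — are dropped and counted.

Vectors carry raw counts. A per-vector L1 normalization is available
(`normalize = TRUE`) but off by default: the classifier standardizes each
feature on the training half, which absorbs overall scale.

## FFT baseline vectors

`make_fft_vectors()` is the spectral control: per channel, discrete Fourier
power at frequencies in $(0, 100)$ Hz (DC excluded, no taper), log taken per
channel with a relative floor ($10^{-20} \times$ the channel's peak power,
guarding all-zero channels), then averaged across channels. Averaging the
*log* power keeps the vector in the same space as the per-channel definition
$v = \log p_{f<100\,\mathrm{Hz}}$; averaging power before the log is the
documented alternative and differs only by Jensen-gap terms. The dimension is
the number of Fourier bins below 100 Hz and so depends only on $\Delta$ and
$S_f$ (199 at $\Delta = 2$ s, 1 kHz).

## Surrogate controls

Three surrogates destroy cross-channel structure while preserving controlled
single-channel properties (`phase_surrogate()`, `stagger_surrogate()`,
`global_stagger_lags()` + `apply_channel_lags()`):

* **Phase**: per channel, Fourier phases of the positive frequencies are
  replaced by i.i.d. uniform draws with Hermitian symmetry enforced; the
  per-channel power spectrum (hence autocorrelation) is preserved exactly.
* **Stagger**: each channel is shifted forward in time by an independent lag
  drawn uniformly from $[0, 0.1\sqrt{12})$ s — a flat distribution whose
  standard deviation is exactly 100 ms — redrawn every time a segment is
  selected.
* **Global stagger**: as above with width 0.5 s, but the lags are drawn once
  per experiment and reused for every segment.

Shifts are implemented *circularly*: no padding policy is needed, segment
length and each channel's sample multiset (and periodogram) are preserved
exactly. The alternative — consuming spare out-of-segment data — is noted but
not the default. Phase surrogation is applied per segment, matching how
vectors are constructed.

## KS stability tracking

`track_stability()` quantifies stabilization over time: pool the $\tau$
values of `pool_fits` consecutive $\delta = 0.5$ s fits at each timestamp and
compare them with a pooled reference distribution (the first verified-awake
stretch) using the two-sample Kolmogorov–Smirnov statistic
(`ks_statistic()`, the supremum ECDF gap; statistic only, no p-value, and
invariant under common monotone transforms). `pool_fits = 20` (10 s of data
per timestamp) is a package default chosen to keep the per-timestamp sample
size at $20 N$ values; it is configurable. A stationary system produces a
flat series at the finite-sample baseline; a stabilizing system drives the
statistic toward 1.

## Classification protocol

`train_svm()` fits a linear-kernel SVM (soft margin $C = 1$ by default) on
per-feature standardized vectors; standardization parameters are estimated on
the training half only, so no information leaks from validation data. The
decision function is reduced to an explicit weight vector and bias, oriented
so positive scores mean "anesthetized"; ties at a threshold predict positive
at score $\ge$ threshold.

`evaluate()` implements the fold protocol: each fold draws a random half of
the training set, trains, and predicts the *entire* validation set (the
held-out complement for within-session validation; a different session's
feature set for cross-session). Fold-to-fold variability therefore comes only
from the training subsample. Errors are reported per fold in percent; the ROC
is built by sweeping the decision threshold over all unique validation scores
pooled across folds, and the AUC is the trapezoid-rule area.
`performance_vs_window()` repeats featurize → evaluate over a grid of
$\Delta$ and feature sources (DS, FFT, DS on surrogate data).

## The synthetic generator

Real anesthesia recordings are not redistributable, so validation runs on
synthetic systems whose ground truth is known exactly. `build_generator()`
assembles $A$ from 2 × 2 rotation–scaling blocks with radius $\rho =
e^{\tau\,dt}$ and angle $\theta = 2\pi f\,dt$ per designed $(f, \tau)$ pair
(plus a scalar block for odd $N$), optionally conjugated by a seeded random
orthogonal matrix so that every channel mixes every mode; the spectrum equals
the design to machine precision either way. `simulate_system()` drives it
with i.i.d. Gaussian innovations (sd 1 by default) from a zero state,
discarding a 2000-sample burn-in.

`make_two_state_recording()` concatenates an awake-like stretch and an
anesthetized-like stretch with a guard gap (the gap continues the awake
simulation, so the only discontinuity is the regime switch itself). The
default regimes share one log-spaced frequency layout across the DS band and
one mixing matrix, and differ only in damping: awake $\tau \in [-20, 0]$ 1/s
(near-marginal), anesthetized $\tau \in [-150, -40]$ 1/s — the qualitative
awake/anesthetized contrast, with occupancy near $\tau = 0$ across the band
in the awake state and mass shifted to strongly negative $\tau$ under
anesthesia. State intervals are pre-trimmed by 5% of their duration per end,
the 30 s margin of a ~600 s-interval protocol scaled to desk-scale
simulations.

The `matched_spectra = TRUE` variant makes the classes *invisible to spectral
features by construction*: the "anesthetized" interval is an independent
realization of the awake regime with fixed per-channel circular shifts (flat
width 0.5 s). Circular shifting preserves each channel's periodogram exactly,
so FFT vectors of the two classes are distribution-matched, while the
cross-channel coupling — and therefore the eigenstructure of fitted VAR
models — differs. This isolates exactly the global, dynamical signal that DS
features claim to capture.

What the generator does *not* emulate: 1/f-like broadband spectra,
nonstationary drug pharmacokinetics, volume conduction, artifacts, or any
nonlinearity. Passing tests on these systems therefore demonstrates that the
*machinery* (estimation, mode mapping, binning, protocol) is correct and that
the method separates regimes that differ in stability or coupling — not that
real recordings of any particular species or anesthetic will separate as
cleanly.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `delta_s` | 0.5 | s | VAR fit window; 500 samples at 1 kHz |
| `k_fits` | 10 | — | sub-window fits pooled per segment |
| `window_s` ($\Delta$) | user | s | segment per feature vector ($\ge \delta$) |
| DS grid | $\tau \in [-250,25]$, $f \in [4,256]$ | 1/s, Hz | 20 × 20, $f$ log2 → dim 400 |
| `n_per_interval` | 500 | — | vectors per state interval (reducible) |
| stagger widths | $0.1\sqrt{12}$ / 0.5 | s | local / global flat lag width |
| `pool_fits` | 20 | — | fits pooled per KS timestamp |
| `C` | 1 | — | SVM soft margin |
| `train_fraction` | 0.5 | — | per-fold training subsample |
| `trim_s` | 5% of interval | s | label margin (synthetic default) |
| `noise_sd` | 1 | a.u. | innovation scale |
| `burn_in` | 2000 | samples | simulation transient discarded |

## Numerical choices and degenerate inputs

* Preprocessing is brick-wall frequency-domain masking (exactly zero-phase,
  idempotent, linear), with a 1 Hz default notch half-width; it is applied to
  whole recordings once, not per segment. The synthetic generator produces
  band-limited signals, so synthetic pipelines may skip it.
* Least-squares rank decisions use `rcond = 1e-10`; rank-deficient windows
  (e.g. all-zero segments) warn and return the minimum-norm fit rather than
  failing, so a single bad window cannot abort a long featurization run.
* Bin edges: `findInterval` with the top edge closed, so a mode exactly at
  $\tau = 25$ or $f = 256$ is kept; $f$-binning operates on $\log_2 f$, which
  maps $f = 0$ to $-\infty$ and naturally drops real modes.
* Equal decision scores at a ROC threshold count as positive; tied scores are
  collapsed to one ROC point.
* Seeds: every stochastic entry point takes an explicit integer seed;
  surrogate lags are redrawn per segment (stagger) or drawn once per
  experiment (global stagger, keyed by seed).

## Desk-scale validation sizes

The shipped tests and the acceptance script run the full pipeline on reduced
problem sizes chosen to exercise every code path while completing quickly:
$N = 8$–16 channels, 1 kHz, state intervals of 20–60 s, 8–25 vectors per
interval, 8–60 folds, and 10–20 generator seeds per property. The guarantees
checked at those sizes (exact recovery, DS ≫ FFT on matched spectra,
surrogate degradation, switch detection, chance-level controls) are the ones
stated above; full-scale runs (128 channels, 500 vectors, $10^3$–$10^5$
folds) use the same code with larger arguments.

## Known limitations

* VAR(1) with white innovations is a local approximation; strongly
  oscillatory innovations or long-memory processes will bias $\tau$ upward.
* The DS grid is fixed; regimes living mostly outside $[-250, 25]$ 1/s ×
  $[4, 256]$ Hz produce sparse vectors (out-of-range modes are counted, not
  binned).
* Within-session fold errors share validation data across folds, so fold
  errors are not independent draws; they quantify training-subsample
  variability only.
* No artifact rejection, re-referencing, or vendor-format readers are
  included.
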