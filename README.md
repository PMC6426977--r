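# dynstab

Single-trial classification of brain state (awake vs anesthetized) from
multichannel electrophysiology, via the **dynamical stability** of windowed
linear models.

The package is for researchers working on depth-of-anesthesia monitoring,
consciousness research, or criticality in neural dynamics who want a complete,
testable implementation of the stability-analysis pipeline: VAR(1) fits,
eigenmode mapping, DS feature vectors, spectral baselines, surrogate controls,
KS stability tracking, and linear-SVM classification — plus a synthetic
generator of linear stochastic systems with designed eigenstructure, so every
claim can be validated against known ground truth without access to animal
recordings.

## The method

On a short window, multichannel activity $y_n \in \mathbb{R}^N$ is modeled as
a first-order vector autoregression

$$ y_{n+1} = A\,y_n + u_n, \qquad u_n \ \text{white noise}, $$

estimated by least squares (SVD pseudoinverse). Each eigenvalue
$\lambda_j = \rho_j e^{i\varphi_j}$ of $A$ is a dynamical mode with frequency
and growth rate

$$ f_j = \frac{|\varphi_j|}{2\pi\,dt}\ \text{(Hz)}, \qquad
   \tau_j = \frac{\log\rho_j}{dt}\ \text{(1/s)}, $$

where $dt$ is the sample period. Awake cortex keeps many modes near marginal
stability ($\tau \approx 0$); anesthesia damps them ($\tau \ll 0$). A **DS
vector** summarizes one data segment of length $\Delta$: the modes of 10
equally spaced 500 ms fits, binned on a fixed 20 × 20 grid
($\tau \in [-250, 25]$ 1/s × $f \in [4, 256]$ Hz, log₂ frequency) and
flattened to 400 counts. Linear SVMs trained on labeled DS vectors classify
single segments; spectral (FFT) vectors and phase/stagger surrogates provide
the controls, and a two-sample Kolmogorov–Smirnov statistic tracks
stabilization over the course of an experiment.

See `vignettes/dynamical-stability.Rmd` for the full account of the model,
parameters, numerical choices and limitations.

## Worked example

```r
library(dynstab)

# a labeled synthetic experiment: near-marginal "awake" regime, strongly
# damped "anesthetized" regime, same frequencies and coupling
sr <- make_two_state_recording(durations_s = c(60, 60), seed = 1)
sr
#> <recording> 16 channels x 130000 samples @ 1000 Hz (130.000 s)
#>          label start_s end_s trim_s
#> 1        awake       0    60      3
#> 2 anesthetized      70   130      3

ds <- make_ds_vectors(sr$recording, sr$intervals, window_s = 2,
                      n_per_interval = 25, seed = 1)
ds
#> <feature_set> 50 x 400 (ds, surrogate=none, Delta=2 s)
#>        awake anesthetized
#>           25           25

report <- evaluate(fold_protocol(n_folds = 50, seed = 1), ds)
report
#> <eval_report> ds/none, Delta=2 s, 50 folds (within_session)
#>   error %: median 0.00 (IQR 0.00-0.00)   AUC 1.0000

ks <- track_stability(sr$recording, reference_window = c(0, 10), step_s = 5)
round(ks$ks, 2)
#>  [1] 0.00 0.04 0.06 0.06 0.08 0.11 0.09 0.08 0.11 0.08 0.04 0.09 0.09 0.45 0.92
#> [16] 0.95 0.95 0.94 0.93 0.92 0.92 0.92 0.93 0.92 0.91
```

Reading the output: given two-second snippets, the classifier separates the
two regimes perfectly (median fold error 0%, AUC 1.0), and the KS series —
comparing each 10 s window's damping-timescale distribution against the
initial awake reference — sits at its ~0.1 finite-sample baseline through the
awake interval, then jumps above 0.9 when the damped regime begins at 70 s.

A command-line front end wrapping the same functions ships in
`inst/cli/dynstab.R` (`simulate`, `preprocess`, `featurize`, `track`,
`train-eval`).

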