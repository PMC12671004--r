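---
title: "Partial modulation index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial modulation index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfc)
```

## 1. The confound

Cross-frequency phase–amplitude coupling between two sites is usually
quantified by the modulation index (MI): bin the low-frequency phase
$\varphi_x$ of site X into $N$ bins, average the high-frequency amplitude
$A_y$ of site Y within each bin, normalize to a probability vector $P$,
and report the normalized KL divergence from uniform,

$$\mathrm{MI} = \frac{\log N - H(P)}{\log N}, \qquad
  P_i \propto \mathbb{E}[A_y \mid \varphi_x \in b_i].$$

MI is a purely associational quantity. Consider the causal graph

$$\varphi_x \;\leftarrow\; \text{(same-band synchronization)}
  \;\rightarrow\; \varphi_y \;\rightarrow\; A_y ,$$

where the low-frequency rhythms of the two sites are transiently
phase-locked and the *local* phase $\varphi_y$ modulates the local
amplitude $A_y$. There is no arrow from $\varphi_x$ to $A_y$, yet MI at
(x-phase, y-amplitude) is large: $\varphi_x$ predicts $\varphi_y$, and
$\varphi_y$ determines $A_y$. In intracranial recordings this situation is
common — low-frequency synchronization and local coupling co-occur during
the same behavioral epochs — so MI systematically overstates cross-regional
coupling.

## 2. Back-door adjustment on binned phases

$\varphi_y$ satisfies the back-door criterion relative to the pair
$(\varphi_x, A_y)$: it blocks the spurious path and is not a descendant of
$\varphi_x$. The adjustment formula for the effect of "setting" the
x-phase to bin $i$ is

$$q_i = \sum_{j=1}^{N} \Pr(\varphi_y \in b_j)\;
        \mathbb{E}\!\left[A_y \mid \varphi_x \in b_i,\,
                                   \varphi_y \in b_j\right].$$

The partial modulation index (PMI) normalizes $q$ to a probability vector
and applies the same KL formula as MI. Two regimes matter:

- **Genuine coupling, no confounding.** If $\varphi_y$ is independent of
  $(\varphi_x, A_y)$, the inner expectation does not depend on $j$ and
  $q_i$ reduces to the ordinary conditional mean: PMI $\approx$ MI.
- **Pure confounding.** If $A_y$ depends on $\varphi_x$ only through
  $\varphi_y$, the stratified means depend on $j$ only, and the marginal
  weighting makes $q$ flat: PMI $\to$ 0.

Both regimes are covered by tests: an oracle on a discrete system where
the adjustment can be computed analytically, a disconnected-confounder
case where PMI must match MI within 10%, and a noise-free fork/chain
construction where PMI must fall below 5% of MI.

### Estimation details

All estimation is done on binned phases ($N = 18$ by default, bin 1
starting at $-\pi$, phases in $[-\pi,\pi)$). The joint table of mean
amplitudes over $(b_i, b_j)$ cells is computed once; empty cells are
excluded and the $\Pr(\varphi_y)$ weights renormalized within each
x-phase row (a `pcfc_empty_cells` warning reports how many). If an entire
x-phase row is empty the adjustment is undefined and
`partial_modulation_index()` raises a classed error
(`pcfc_undefined_pmi`) carrying the joint counts, rather than guessing.

```{r pmi-demo}
set.seed(1)
n <- 5000
phy <- runif(n, -pi, pi)
phx <- ifelse(runif(n) < 0.8, phy, runif(n, -pi, pi))  # sync 80% of time
amp <- 1 + 0.6 * cos(phy) + 0.1 * rexp(n)              # local coupling only
mi  <- modulation_index(amp, bin_phases(phx, 18), 18)$value
pmi <- suppressWarnings(
  partial_modulation_index(amp, phx, phy, n_bins = 18))$value
c(mi = mi, pmi = pmi, ratio = pmi / mi)
```

## 3. Signal decomposition

Phases and amplitudes come from zero-phase FIR band-pass filtering
(Hamming window, order $\lceil 3 f_s / f_\text{lo} \rceil$ rounded up to
even, applied forward and backward with `signal::filtfilt`) followed by
the FFT-based analytic signal. Filtering both ways doubles the stop-band
attenuation and cancels group delay exactly, which matters because a
phase-lagged filter would smear amplitude into neighboring phase bins.
`decompose()` flags `order + 1` samples at each edge as invalid; every
downstream computation drops them.

Default bandwidths: 2 Hz around the phase frequency, and twice the phase
frequency around the amplitude frequency — the amplitude band must be wide
enough to contain the modulation side-bands at $f_\text{amp} \pm
f_\text{phase}$, otherwise the envelope cannot fluctuate at the modulating
rate and coupling is invisible by construction.

## 4. Surrogates and cluster correction

The null distribution comes from time-shift surrogates: the amplitude
series is circularly rotated by a uniform random offset of at least 1 s.
This preserves both marginal spectra and the amplitude distribution while
destroying the phase–amplitude alignment. The p-value uses the add-one
permutation form $p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n)$.
One shared set of offsets is used across all comodulogram cells so that
the per-surrogate grid is a proper draw from the joint null.

Cluster correction follows the max-statistic permutation approach:
threshold per-cell p-values at `cluster_alpha`, form 4-connected clusters,
score each by the sum of observed values, and compare against the null
distribution of the maximum cluster mass recomputed within each surrogate
draw. A cluster survives when its corrected p-value is at most `alpha`.

Calibration is tested directly: under an independent phase/amplitude null
the per-cell test rejects at 5% within binomial tolerance over 500
repetitions, and on white-noise channels the cluster-corrected
comodulogram almost never reports a surviving cluster.

## 5. The validation datasets

`simulate_dataset1()` and `simulate_dataset2()` generate paired 30 s
recordings (1 kHz) in three equal segments. Per segment and per role, a
low frequency is drawn from $\mathcal{N}(13, 1)$ Hz and a lag from
$\mathcal{N}(0, 1/f)$ s; the high frequency is fixed at 150 Hz, the
modulated term is $k \sin(\theta + \pi/4)\sin(2\pi f_h t)$ with $k = 1$,
plus unit white noise (or, with `waveform = "lfp_like"`, a mixed
1/f-aperiodic + white background normalized to unit RMS).

- **Dataset 1 (confounded):** segment 2 contains same-band phase
  synchronization between X and Y *and* local phase–amplitude coupling at
  Y at the same time. MI sees cross-regional coupling; none exists.
- **Dataset 2 (genuine):** synchronization occupies segment 2 while
  cross-regional coupling occupies segment 3, so the association is real.

The headline contrast — MI significant on both datasets, PMI significant
only on dataset 2 — is reproduced by `run_contrast_experiment()` and
asserted in the test suite. Drawing the low frequency *per segment* is
load-bearing: with a single whole-record frequency the synchronization
segment phase-locks to the coupling segment and the time-shift null
degenerates.

With the LFP-like background the spurious MI and the genuine PMI effects
replicate robustly, but suppression of the dataset-1 PMI below the
cluster threshold depends on the (unspecified) white-to-aperiodic power
ratio; the default `white_power_fraction = 0.5` is a neutral choice, not
a tuned one, and the tests only assert the parts that replicate at rate
1.0.

## 6. Sensitivity sweeps and an honest failure

`run_sweep()` repeats the contrast across a grid of noise levels,
durations, or bin counts (50 repeats × 200 surrogates each by default)
and reports detection rate on dataset 2 and false-alarm rate on
dataset 1. A grid point *qualifies* when detection $\ge$ 0.8 and the
false-alarm rate stays within a one-sided 95% binomial tolerance of the
nominal level, $\alpha + 1.645\sqrt{\alpha(1-\alpha)/n_\text{repeats}}$.

The duration sweep qualifies from short durations upward. The bin-count
sweep at 30 s does **not** qualify at any swept $N$, and this is a real
property of the estimator, not a bug: binned stratification leaves a
small deterministic residual on the confounded dataset (the within-bin
distribution of $\varphi_y$ still varies slightly with $\varphi_x$ inside
each stratum). The residual is orders of magnitude below the genuine
effect, but it is *deterministic* — time-shift surrogates do not contain
it — so with enough data the surrogate test resolves it and the
false-alarm rate climbs with duration. At 5–10 s the test is calibrated;
at 30 s it is not. The package reports this behavior as measured
(`min_qualifying_duration()`, `max_qualifying_bins()`), and the
corresponding acceptance test is expected to fail rather than being
weakened. Practical advice follows directly: with long recordings, either
analyze in moderate windows and combine, or compare the observed PMI
against a confound-matched surrogate rather than the generic time-shift
null.

## 7. Directed connectivity

Two complementary directed measures are included for the follow-up
question "which way does the low-frequency influence flow?":

- **Directed transfer function** (`dtf_significance()`): a bivariate VAR
  model fitted by least squares (order by AIC up to 20), transfer matrix
  $H(f) = A(f)^{-1}$, normalized so each receiving row sums to 1.
  Significance by Fourier phase-randomization surrogates with Bonferroni
  correction over two directions × five frequency bands.
- **Phase transfer entropy** (`transfer_entropy()`): plug-in estimate on
  binned phases, $TE_{X \to Y} = I(Y_t ; X_{t-\ell} \mid Y_{t-\ell})$ in
  bits, with a shuffled-source baseline quantifying estimator bias and a
  `pcfc_sparse_states` warning when state occupancy is too thin for the
  plug-in estimate to be trusted.

Both recover the planted direction of a unidirectional AR system in the
test suite; both stay silent on independent channels.
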