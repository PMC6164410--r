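---
title: "Classifying chemical stimuli from plant electrical signals with curve-fit coefficient features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying chemical stimuli from plant electrical signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytovolt)
```

## The problem and the model

Higher plants propagate electrical signals — action potentials, variation
potentials and system potentials — in response to environmental stress.
Recorded extracellularly with stem electrodes at 10 Hz, the post-stimulus
response to a chemical insult (soil NaCl, dilute H₂SO₄, airborne O₃) is a
slow millivolt-scale drift over minutes to hours whose global shape differs
between stimuli. `phytovolt` classifies the stimulus from a single
whole-duration series.

The central idea is to compress each series into the coefficient vector of a
whole-series parametric fit and classify in that coefficient space. Four
families are fitted on normalized time $x \in [0,1]$:

* polynomial $\hat y = \sum_{i=1}^{n+1} P_i\,x^{\,n+1-i}$, degree $n = 1..9$;
* sum of Gaussians $\hat y = \sum_{i=1}^{n} a_i e^{-((x-b_i)/c_i)^2}$, $n = 1..4$;
* Fourier series $\hat y = a_0 + \sum_{i=1}^{n} a_i\cos(i\omega x) + b_i\sin(i\omega x)$, $n = 1..4$, $\omega$ free;
* exponentials $\hat y = a e^{bx}$ or $a e^{bx} + c e^{dx}$.

The cap of 10 coefficients (degree 9) keeps the feature space small relative
to realistic series counts per class — the recording campaign this package's
defaults emulate had 16, 52 and 343 series for the three stimuli
(`reference_study_counts()`), and a 10-dimensional Gaussian classifier is
already at the edge of what 16 series support. Coefficient vectors are always
used whole: there is no per-coefficient ranking or selection, so the feature
space is exactly the model family's parameter space.

Fit quality is screened with $R^2 = 1 - SS_{res}/SS_{tot}$. $R^2 \le 1$
always, and negative values are meaningful: the model is worse than the
horizontal mean line, which is precisely the behaviour that disqualifies the
Gaussian and exponential families on trend-like signals. Families whose
median $R^2$ sits near or below zero contribute noise-like coefficients and
are screened out before classification.

### Classifiers

Five binary discriminants are implemented directly from their definitions
(`train_discriminant()`), not wrapped from another package:

* **lda** — pooled within-class covariance
  $\Sigma_p = \frac{(n_A-1)S_A + (n_B-1)S_B}{n_A+n_B-2}$; the explicit
  linear form $y = w^\top f + b$ with $w = \Sigma_p^{-1}(m_A - m_B)$ is
  exposed and tested to agree with the Gaussian-score form to 1e-10.
* **qda** — per-class covariance. The quadratic discriminant is evaluated as
  per-class Gaussian log-densities plus log-priors; this is algebraically
  identical to the expanded form with $M(M+1)/2$ pairwise-product terms and
  numerically far better behaved.
* **diaglinear / diagquadratic** — the same with off-diagonal covariance
  entries zeroed (feature-independence, i.e. naive Bayes).
* **mahalanobis** — assign to the class with smaller
  $r_i = (x - m_i)^\top \Sigma_i^{-1} (x - m_i)$; a pure distance rule, no
  priors. With identity covariance it reduces to nearest-centroid, a
  property the tests exercise on random instances.

Priors default to empirical class frequencies (`priors = "uniform"` is
available), matching the strong class imbalance of real campaigns.
Covariances are symmetrized and, when near-singular — unavoidable with 10
features and few series, or in diagonal-free folds — ridged with
$\lambda\,(\mathrm{tr}\,\Sigma / M)\,I$, $\lambda = 10^{-6}$ escalating
tenfold until positive definite. This is the smallest perturbation that
guarantees definiteness; $\lambda$ is a user parameter.

Ties at exactly equal scores go to the first-listed class of the pair; the
signed margin (first-class score minus second-class score) is returned for
downstream tie-breaking.

### Evaluation and selection

`loocv()` runs one fold per series; the z-score normalizer is refitted
inside every fold by default, so the held-out series never influences the
scaling it is judged against (`normalize = "global"` reproduces the simpler,
leaky reading of one shared normalization; both modes exist because
published pipelines often leave this unstated). Counts aggregate with the
first stimulus of the pair as the positive class. Metrics with a zero
denominator are reported as `NA`, never coerced to 0 or 1 — on a
single-class prospective set, "specificity" is not a number.

`select_best()` maximizes accuracy, breaking ties by the larger
$\min(\text{sensitivity}, \text{specificity})$ (accuracy alone can look
excellent while one class is systematically misclassified), then by lower
model order, then by classifier simplicity
(lda < diaglinear < qda < diagquadratic < mahalanobis).

### One-versus-one tree

The three per-pair winners become a three-class predictor
(`build_ovo_tree()`): each pair model carries its own (family, order)
features and its own normalizer, the union of required fits forming the
"test matrix" a new series must supply. Prediction is by majority of the
three pairwise votes; a 1-1-1 cycle is broken by the vote of the pair model
with the largest absolute margin. A sequential-elimination traversal was
considered and rejected as the default: it makes the prediction depend on an
arbitrary pair ordering, whereas majority voting is permutation-invariant (a
property the tests assert).

## The simulator: what it emulates and what it does not

Because the original recordings are not deposited, `simulate_signals()`
generates class-conditional post-stimulus series:

$$v(t) = s \cdot g \cdot P(x(t)) + \varepsilon(t)$$

with $P$ a per-class polynomial trend on normalized time, $g$ a lognormal
amplitude multiplier, $s = -1$ with a configurable polarity-flip probability
(system-potential-type responses reverse polarity relative to action and
variation potentials), and $\varepsilon$ stationary AR(1) noise.

Defaults of `default_benchmark_config()`, chosen once as the study
conditions:

| parameter | value | rationale |
|---|---|---|
| trend family | fixed degree-5 polynomials, one distinct shape per class | makes noiseless parameter recovery exact and matches the winning feature family |
| sampling rate | 10 Hz | the field-standard rate for these slow signals |
| duration | uniform 60–120 s per series | durations vary in practice; randomizing them exercises the duration-invariance that normalized-time fitting provides |
| amplitude jitter | lognormal, σ = 0.15 | plant-to-plant response-magnitude variation |
| AR(1) φ | 0.95 | electrophysiological baselines are strongly autocorrelated; white noise would flatter the classifier |
| noise level | stationary sd = peak-to-peak / 25 ("high", SNR ≥ 20) or / 1.5 ("low", SNR ≤ 2) | the innovation sd is scaled by $\sqrt{1-\varphi^2}$ so the SNR refers to realized noise |
| polarity flips | 0 in the benchmark | reversed polarity is a real phenomenon and is exercised by dedicated simulator tests, but the benchmark measures separability of the canonical morphologies |

What passing tests on this benchmark show: the pipeline recovers known
generative structure, the classifiers agree with independent oracles, and
under clean class-distinct trends the end-to-end system reaches high
leave-one-out and prospective accuracy. What they do **not** show: that real
plant responses to NaCl, H₂SO₄ and O₃ are this separable. Real recordings
have nonstationary baselines, electrode drift, variable stimulus onsets and
within-class morphology families that a single polynomial template does not
capture. Benchmark template shapes are conventions, not claims about plants.

A note on the low-separation setting: even at SNR ≤ 2 a whole-series fit
averages the noise over a hundred or more samples, so class trends remain
partially separable and accuracy sits between chance and perfect rather than
at chance. The chance-level control in the test suite is therefore a label
permutation (accuracy inside the central 99% binomial band around 0.5), not
the low-SNR benchmark.

## Numerical choices

* **Normalized time.** All fitting uses $x \in [0,1]$. Raw seconds would
  make a degree-9 Vandermonde on an hours-long series numerically unusable
  (condition numbers beyond 1e80) and would make coefficients incomparable
  across unequal durations. This is a deliberate departure from fitting raw
  time axes: it changes the coefficient values but not the family's
  information content, and it is applied identically to every series.
* **Polynomial solver.** QR least squares, not explicit normal equations;
  the normal-equations form appears only as the independent oracle in tests,
  at low degree where it is itself accurate.
* **Gaussian initialization.** Peaks at the $n$ largest local maxima of a
  9-point moving average of $|y - \mathrm{median}(y)|$, widths from
  half-prominence, signed amplitudes from the raw deviations; widths
  constrained positive. Deterministic, so repeated fits are identical.
* **Fourier.** Separable structure: for fixed $\omega$ the linear
  coefficients are a QR solve; $\omega$ starts at the dominant nonzero DFT
  bin and is refined by bounded 1-D minimization over
  $[0.5\,\omega_0,\,2\,\omega_0]$.
* **Exponential.** Log-linear regression on the shifted-positive response
  initializes $(a, b)$; the two-term fit starts at rates $(b, 5b)$.
* **Convergence.** Levenberg–Marquardt, relative cost tolerance 1e-10, max
  400 iterations. Non-converged fits are returned with their achieved $R^2$
  and a `converged = FALSE` flag, never discarded: a poor fit is a result
  (it is how whole families get screened out), not an error.
* **Degenerate $R^2$.** A constant series has $SS_{tot} = 0$; the package
  defines $R^2 = 1$ when residuals are numerically zero and 0 otherwise,
  preserving perfect-fit semantics without a 0/0.
* **Robust fitting** (least-absolute-residual, bisquare) is deliberately not
  implemented; ordinary least squares is the studied configuration.

## Problem sizes

The shipped tests and the acceptance script run the benchmark at 3 classes ×
20 series (60 series, 600–1200 samples each) for the headline accuracy, and
smaller 4–8-series-per-class configurations with 15–40 s durations for
structural and property tests. These sizes were chosen so the full suite
documents the method's behaviour in seconds while remaining large enough for
stable covariance estimates (16+ training series per class against 10
features in every leave-one-out fold of the headline run).

## Known limitations

* Binary discriminants only; multiclass is always via the one-versus-one
  tree, which does not extend gracefully far beyond a handful of classes.
* No uncertainty on coefficients or on accuracy estimates; the pipeline
  reports point metrics, as leave-one-out aggregation has no simple
  variance.
* The simulator's single-template-per-class design cannot represent
  multimodal response morphologies; polarity reversal is its only
  within-class structural variation.
* `fit_fourier` treats $\omega$ per series; signals whose dominant DFT bin
  is a poor frequency guess (e.g. strong trend leakage) may settle in a
  local optimum — the screening relies on relative, not optimal, fit
  quality.
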