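---
title: "EASI: per-ion linear modeling of replicate EI mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EASI: per-ion linear modeling of replicate EI mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easispec)
```

## The problem

A unit-resolution electron-ionization (EI) mass spectrum of a pure compound
is, in practice, a vector of relative fragment-ion abundances normalized to
the base peak at 100 %. Library identification traditionally compares a
query spectrum against a single *exemplar* — often the mean ("consensus")
spectrum of replicate reference measurements — using a similarity score such
as the weighted cosine. This fails in a predictable way: replicate spectra
of one compound are not i.i.d. noise around a mean. Fragment abundances
co-vary strongly (pairwise correlations between normalized ion pairs
commonly exceed 0.9) because the whole fragmentation pattern responds
jointly to the effective internal-energy state of the ion source. A query
measured on a different instrument, or decades later, is systematically
displaced along that covariance axis, so it can sit far from the consensus
spectrum while still being an unimpeachable positive — and a diastereomer
can sit closer to the consensus than a genuine positive does.

`easispec` implements the EASI approach: instead of a fixed exemplar, each
panel ion's abundance is predicted *from the other ions measured in the
same query spectrum*, through per-ion linear models fitted on replicate
training spectra. Because the models are linear, they extrapolate to
instrument states outside the training range; a true positive from a
shifted instrument still satisfies the inter-ion linear law and produces
small residuals, while a negative violates it no matter where it sits.

## Model and fitting

Let $x_1, \dots, x_K$ be the normalized abundances of the $K$ most
abundant panel ions (default $K = 20$, selected from the training
consensus; ties broken toward lower $m/z$). For each target ion $j$ the
training replicates provide a linear model

$$\hat{x}_j = \beta_{j0} + \sum_{c \ne j} \beta_{jc}\, x_c,$$

fitted by bidirectional stepwise least squares: at each step the candidate
with the smallest partial-F $p$-value enters if $p < p_\text{enter}$
(default 0.05), then any included covariate with $p > p_\text{remove}$
(default 0.10) is removed, until no change. These thresholds are the
probability-of-F convention of classical stepwise packages. Zero-variance
covariates — above all the base peak, which is 100 by construction in every
spectrum — are excluded from candidacy, and a zero-variance target yields a
constant model with $R^2$ defined as 0. Candidates that would render the
design singular are refused and selection continues without them. On
replicate data of the kind the generator produces, the selected models
explain well over 90 % of each ion's variance with a handful of covariates.

Predictions are deliberately **not** clipped to $[0, 100]$: for
off-pattern spectra the linear models happily predict negative or >100 %
abundances, and that misbehavior is itself diagnostic of a negative.

Two predictors are compared throughout:

* **consensus** — $\hat{x}_j$ is the training-set mean of ion $j$,
  identical for every query;
* **easi** — $\hat{x}_j$ from the query's own measured covariates.

## Comparing measured and predicted spectra

Four measures condense the $K$ residuals
$\varepsilon_j = \hat{x}_j - x_j$ of one query into one score:

* **MAR**, $\frac{1}{K}\sum_j |\varepsilon_j|$ (% of base peak) — preferred
  over an RMS error because it does not scale with $K$;
* **Euclidean distance**, $\sqrt{\sum_j \varepsilon_j^2}$;
* **dot product**, the cosine between predicted and measured vectors;
* **NIST-style score**, the cosine between weighted vectors
  $a_j^{x}\,(m/z_j)^{y}$ with $x = 0.6$, $y = 3$, scaled so a
  self-match is exactly 999. The score is the plain (not squared) cosine;
  the classic 996-and-above thresholds on the 999 scale are consistent with
  that reading. Negative EASI predictions are floored at 0 only inside this
  weighting (fractional powers of negatives are undefined); MAR, Euclidean
  and cosine use the raw values.

Independently of any per-ion modeling, the Mahalanobis distance
$d = \sqrt{(\mathbf{x}-\bar{\mathbf{x}})^\top C^{-1}(\mathbf{x}-\bar{\mathbf{x}})}$
measures how many multivariate standard deviations a query sits from the
training cloud, using the training mean $\bar{\mathbf{x}}$ and sample
covariance $C$ ($n-1$ denominator). Zero-variance channels are dropped
before inversion, so a 20-ion panel with a constant base peak leaves 19
retained dimensions; the squared distance can be referred to a
$\chi^2_{19}$ distribution, whose upper-5 % critical value is 30.1. The
solve goes through the Cholesky factor of $C$ rather than an explicit
inverse; when $n \le K$ the covariance is singular and the model falls
back, with a warning, to the Moore–Penrose pseudo-inverse.

## Binary classification

Labeled scores become classifiers by thresholding (inclusive on the
positive side: $\ge$ for similarity scores, $\le$ for dissimilarities).
`roc_curve()` sweeps every distinct score plus infinite sentinels and
integrates by the trapezoid rule; with one point per distinct score this
AUC equals the Mann–Whitney probability that a random positive outscores a
random negative, ties counted ½ — an identity the test suite verifies
exactly against an $O(n^2)$ pairwise oracle. Precision–recall curves omit
thresholds with no predicted positives, where precision is undefined.
`zero_fp_threshold()` returns the most permissive threshold admitting no
false positive, placed at the midpoint between the extreme known-negative
score and the nearest admissible known-positive score (the placement of a
threshold between two observed scores is a convention; the midpoint makes
it deterministic).

The supervised classifier `fit_residual_logit()` runs bidirectional
stepwise *logistic* regression on the per-channel EASI residuals,
with likelihood-ratio (not Wald) entry/removal tests — Wald statistics
degenerate exactly in the situation of interest, when a residual channel
separates the classes completely. Known negatives are coded 1, so the
target compound sits at low fitted probability and the call is positive
when $p < 0.5$ (a probability exactly at the threshold is classified
negative). Under complete separation, where maximum likelihood diverges,
the selected model is refit by Firth-penalized likelihood (Newton
iteration on the hat-value-corrected score) and the `method` tag records
`"firth"`.

## The synthetic generator

No public corpus of replicate forensic EI spectra with truth labels exists,
so the package ships a generator (`generator_spec()`, `cocaine_like_spec()`)
whose output has exactly the statistical structure the method assumes, and
which all statistical tests draw from:

* each replicate draws one latent factor $E \sim N(\mu, \sigma_E)$ — the
  effective instrument state — and sets every channel's raw intensity to
  $\alpha_i + b_i E$ plus $N(0, \sigma_\text{noise})$ noise, floored at 0;
* the default panel uses 20 cocaine-like channels (82, 182, 94, 96, 105,
  152, 155, 198, 272, 303, ...) so examples read naturally; the intensity
  values are arbitrary synthetic choices, not measured cocaine data. The
  base peak (m/z 82) has slope 0; the channels at m/z 77, 94 and 105 carry
  negative slopes (anticorrelated with the rest), mirroring the sign
  pattern seen between low-mass fragments and the high-mass ions in real
  replicate sets;
* slope magnitudes (2–6 % per latent unit) against the default noise
  ($\sigma_\text{noise} = 0.5$ % of base peak) give pairwise inter-ion
  correlations with median above 0.9, the regime the method is designed
  for;
* a "lab shift" batch moves $\mu$ by a chosen offset in training-sd units,
  emulating spectra from other instruments; a shift of 2 sd is used as the
  canonical external-lab condition;
* *distinct* negatives have their own channels and an uncorrelated
  pattern; *diastereomer-like* negatives follow the positive law but with
  the 94/96 abundance ratio multiplied by 0.55 and the 152/155 ratio by
  1.5 — stand-ins for the stereoisomer pairs whose spectra differ only in
  a few channel ratios.

What the generator does *not* emulate: non-linear saturation, isotope
structure, chromatographic or matrix interferences, concentration effects,
and multi-dimensional instrument drift (a single latent axis is the
default; that choice matches the kinetic picture of one effective
internal-energy coordinate). Tests passing on generator data therefore
demonstrate the algorithmic claims — EASI's dominance over the consensus
under systematic shifts, separability of ratio-shifted negatives — not
performance on casework spectra.

## Default problem sizes and numeric choices

Training runs in the tests and examples use $n = 128$ replicates (the
quick-start default in `simulate_replicates()` examples is $n = 30$, about
the point where the per-ion models start beating the consensus clearly);
query batches are 10–40 spectra; statistical properties are checked over
100 seeded trials. All randomness flows through explicit seeds and the
generator restores the caller's RNG stream.

Numerical conventions worth knowing:

* nominal binning rounds half-*up* (`floor(x + 0.5)`), summing intensities
  within a bin (summing conserves ion current; maxima would not);
* zero variance means variance below $10^{-10}$ on the % scale;
* writers emit 6 significant digits; MSP round trips are lossless at that
  precision;
* panel ties in mean abundance break toward lower $m/z$;
* missing panel channels in a query are true zeros, not missing values —
  the absence of an expected fragment is evidence.

## Limitations

The stepwise selections inherit the usual instabilities of stepwise
inference: with fewer than `covariates + 10` training rows a warning is
issued and selected supports may vary between seeds (coefficients of
correlated covariates are individually unidentifiable under a
single-latent design even when predictions are excellent — which is why
the parameter-recovery tests check the *effective* latent slope
$\sum_c \beta_{jc} b_c$ rather than individual coefficients). The
Mahalanobis classifier assumes the training set spans the full variance of
future positives and degrades for out-of-range instruments, which is
precisely the regime where the per-ion linear models retain their
advantage. Probability calibration of scores (likelihood ratios from
kernel densities) is out of scope.
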