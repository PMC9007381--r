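---
title: "Beta-diversity under the stochastic logistic model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-diversity under the stochastic logistic model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slmbeta)
```

## The model

`slmbeta` treats each OTU (operational taxonomic unit) in a microbial
community as an independent stochastic logistic process with environmental
noise,

$$\dot\lambda_i \;=\; \frac{1}{\tau}\,\lambda_i\Big(1-\frac{\lambda_i}{K_i}\Big)
  \;+\; \sqrt{\frac{\sigma_i}{\tau}}\;\lambda_i\,\xi_i(t),$$

where $\xi_i$ is Gaussian white noise, $K_i$ sets the OTU's typical relative
abundance ("carrying capacity", known only up to a sample-wide compositional
constant), and $\sigma_i$ the intensity of the environmental fluctuations.
For $\sigma < 2$ the process is stationary and the abundance fluctuation
distribution is a Gamma law with shape $2/\sigma - 1$ and rate
$2/(\sigma K)$, so that

$$\langle\lambda\rangle = \frac{K(2-\sigma)}{2}, \qquad
  \mathrm{var}(\lambda) = \frac{\sigma\,\langle\lambda\rangle^2}{2-\sigma}.$$

The squared coefficient of variation, $\sigma/(2-\sigma)$, is independent of
$K$: across OTUs sharing $\sigma$, variance scales as the mean squared
(Taylor's law with exponent exactly 2). `taylor_law_fit()` checks this on
closed-form or empirical moments.

`slm_params()` accepts $\sigma = 0$ (the plain logistic equation, useful for
validating the integrator against its fixed point) but the stationary-law
functions reject it, since the Gamma shape diverges there.

## Generating pairs of communities

Two communities are modelled as two draws of the same ecosystem whose
similarity is controlled by a single knob: the Pearson correlation
$\rho_K$ of their log carrying capacities. The recipe
(`generate_pair()`) is:

1. draw $S$ pairs $(\log K_i^A, \log K_i^B)$ from a bivariate normal with
   common marginal $\mathcal N(\mu, s^2)$ and correlation $\rho_K$;
2. draw one $\sigma_i^2$ per OTU from an exponential distribution, shared by
   the two communities;
3. draw true abundances $\lambda_i$ from the stationary Gamma law of each
   community;
4. sequence each community by a multinomial draw of $N_{\mathrm{reads}}$
   reads with probabilities $\lambda_i/\sum_j\lambda_j$.

Defaults follow the reference simulation conditions used throughout the
package's tests: $S = 10^4$ OTUs, $\mu = -19$, $s = 5$ (natural logs),
exponential mean $0.9$ for $\sigma^2$, and $3\times10^4$ reads per sample.
(When *fitting* these distributions to data rather than simulating, the
corresponding empirical estimates take their place; the defaults are the
simulation targets.) Because the lognormal spans many orders of magnitude,
only a small fraction of the $S$ OTUs — those with relative abundance above
roughly $1/N_{\mathrm{reads}}$ — are ever observed; sparsity in the count
tables is produced entirely by sampling, not by absence.

Choices worth making explicit:

* **$\sigma^2$ rejection.** Exponential draws with $\sigma^2 \ge 4$ would
  violate stationarity; they are rejected and redrawn (about 1.2% of draws
  at mean 0.9), which preserves the exponential shape below the physical
  bound. The closed-form mean of the truncated law, $\approx 0.848$ at mean
  parameter $0.9$, is what `sample_sigmas()` is tested against.
* **Same-community pairs.** To mimic two time points of one community, a
  pair shares its $K$ vector ($\rho_K = 1$) and its abundance draws are
  correlated at a target Pearson level (0–0.5). The coupling uses a Gaussian
  copula; because a copula's latent correlation does not equal the Pearson
  correlation of the Gamma marginals, the latent value is calibrated
  numerically: the latent-to-Pearson map is tabulated by Monte Carlo on a
  grid of Gamma shapes (Pearson correlation is scale-free, so only the
  shared shape matters) and inverted by monotone interpolation. Shapes are
  clamped to $[0.05, 100]$ for the calibration; outside that range the
  quantile transform underflows double precision (such OTUs are
  unobservable at any realistic depth) or the map is flat.
* **Underflow floor.** Gamma draws with very small shapes ($\sigma \to 2$)
  can underflow to an exact floating-point zero; since every OTU is present
  in a community by construction, such draws are floored at the smallest
  positive normalized double. This is a representation fix, not a model
  change: it only affects abundances below $10^{-300}$.
* **Unequal depths** are supported (`n_reads_A`/`n_reads_B`) although the
  reference analyses use a single depth; all abundance-based metrics
  normalize by each sample's own total.

## Beta-diversity measures

`all_metrics()` computes, from two count vectors on a shared OTU index:
Jaccard, Sørensen, Whittaker ($2|S^A\cup S^B|/(|S^A|+|S^B|)$), effective
Whittaker (the same ratio on exponential-Shannon "effective species"
numbers, with the mixture $m = (x^A+x^B)/2$ in the numerator),
Morisita–Horn, Horn, Bray–Curtis, and the dissimilarity/overlap pair of
dissimilarity–overlap analysis. Conventions:

* $0\log 0 := 0$ everywhere; all logarithms are natural, so the rJSD
  dissimilarity is bounded by $\sqrt{\log 2}\approx 0.8326$.
* Sums run over the union of observed OTUs (OTUs absent from both samples
  contribute nothing).
* The dissimilarity renormalizes abundances on the *shared* OTUs only. When
  the two samples share no OTU it is undefined: `dissimilarity_rjsd()`
  returns `NA` with a reason attribute instead of throwing, so ensemble
  analyses can count and skip such pairs.
* The effective Whittaker index exceeds 1 for near-disjoint supports (it
  reaches 2 for disjoint single-read samples); it is reported as computed.

Every metric is validated in the test suite against an independent,
deliberately naive set-based reimplementation, against hand-computed values
on a 3-OTU example, and (for Bray–Curtis, Jaccard and Morisita–Horn)
against `vegan`.

## Estimating $K$ and $\sigma$ from time series

The sampled variance of relative abundance mixes true fluctuation variance
with multinomial sampling noise. The sampling-corrected estimator

$$\widehat{\mathrm{var}}(\lambda) = \frac{1}{|T|}\sum_{t}
  \frac{x(t)\,(x(t)-1)}{N(t)\,(N(t)-1)}
  - \Big(\frac{1}{|T|}\sum_t \frac{x(t)}{N(t)}\Big)^2$$

is unbiased for the empirical variance of the true abundances (for counts
$x(t)$ binomial or multinomial at depth $N(t)$), and can be negative when
counts are mostly 0 or 1 — such OTUs are excluded from parameter estimation,
with exclusion counts reported. Moment inversion gives
$\hat\sigma = 2c/(1+c)$ and $\hat K = \hat m(1+c)$ with
$c = \hat v/\hat m^2$, the exact inverse of the stationary moments.

The cross-OTU distributions are fitted by maximum likelihood:
`fit_exponential_sigma2()` (sample mean) and `fit_truncated_lognormal()`,
which renormalizes the lognormal on $(c, \infty)$ to account for the
detection cutoff and optimizes $(\mu, \log s)$ by Nelder–Mead plus BFGS
polish from a moment start (relative tolerance $10^{-12}$ on the negative
log-likelihood), with a profile grid search as a fallback. The cutoff
defaults to $10^{-4.5}$ but is an explicit parameter, as its proper value
tracks the sequencing depth of each environment.

A genuine limitation worth knowing: when the cutoff sits deep in the upper
tail of the distribution (as it does at $\mu=-19$, $s=5$, where only ~4% of
OTUs are observable), the truncated likelihood has a nearly flat
$\mu$–$s$ ridge and the MLE's sampling error is large — of order
$\pm 1$ in $\mu$ even with $10^4$ observed values. The estimator is
consistent (the test suite checks that its error shrinks with $n$ under
mild truncation), but tight recovery of deeply truncated parameters
requires far more data than a single host's OTU set provides. Reported
fits should always be read together with `n_used`.

## Inferring $\rho_K$ for a pair of samples

$\rho_K$ is not observable directly, but in simulation it has a smooth
relationship with the Spearman correlation $s$ of the two samples'
abundances. `calibrate_rho_spearman()` simulates an ensemble of pairs with
known $\rho_K$, computes $s$ per pair, and fits the least-squares quadratic
$\rho_K = a_0 + a_1 s + a_2 s^2$; `infer_rho_K()` evaluates it on data.

Two conventions are fixed here and used identically in calibration and
inference (only their consistency matters):

* **Spearman input set**: all OTUs observed in at least one of the two
  samples, absences entered as zeros, ties averaged. With this convention
  the default calibration reproduces the reference quadratic
  $\rho_K \approx 0.92 + 0.34\,s - 0.48\,s^2$ within stochastic tolerance,
  which is the package's acceptance check.
* **Calibration ensemble**: the default mirrors the reference 200-pair
  ensemble — 100 same-community pairs (abundance correlation 0–0.5,
  $\rho_K = 1$) plus 100 across-community pairs ($\rho_K$ uniform on
  $[0.5, 1]$).

The fitted quadratic is non-monotone (vertex near $s \approx 0.35$), so
inversion outside the fitted Spearman range is unreliable: `infer_rho_K()`
flags extrapolation rather than guessing, and clips $\hat\rho_K$ to
$[0, 1]$.

## Dissimilarity–overlap analysis

Before sampling, every generated pair has overlap exactly 1 — dissimilarity
and overlap are structurally independent in the model. After multinomial
sampling, a negative relationship between them appears at high overlap:
rare OTUs drop out asymmetrically, and both the overlap and the
shared-OTU dissimilarity respond to $\rho_K$ through the same sampling
cutoff. `compute_doc()` evaluates both regimes on the same ensemble, which
is the package's demonstration that a decreasing DOC requires no
ecological coupling between the two measures — finite sampling suffices.

`doc_slope_high_overlap()` quantifies the high-overlap end (default
threshold 0.9; least-squares slope with a percentile bootstrap over pairs),
and `binned_average()` produces curve summaries with equal-width bins along
either axis (default 20 bins; the axis choice matters because the
high-overlap region is dense, and binning along dissimilarity resolves it
better). Undefined dissimilarities are excluded from slopes and bins, with
counts carried through. When pairs with small overlap are included (low or
negative $\rho_K$), the binned DOC is non-monotone — it rises and then
falls, an inverse-U — which the test suite asserts on a wide-$\rho_K$
ensemble.

## Synthetic data: what it does and does not emulate

The generator reproduces the statistical skeleton of real gut-microbiome
count tables: lognormal carrying capacities, exponential $\sigma^2$, Gamma
abundance fluctuations, multinomial sampling at realistic depth, and
pairwise $K$ correlations. It deliberately omits: species interactions,
multi-attractor dynamics, colored environmental noise, time-resolved
coupling between the members of a pair (pairs are stationary snapshots;
the time-series generator covers single communities), phylogenetic
structure in the $K$ correlations, and any difference in $\sigma$ between
communities. Tests passing on this generator therefore validate the
sampling-and-fluctuation machinery, not those ecological mechanisms.

The time-series fixture (`simulate_time_series()`) adds one design choice:
the focal OTUs' $K$ are read as true relative abundances and a single
filler row `OTU_rest` absorbs the remaining reads, so each focal OTU's
counts are marginally $\mathrm{Binomial}(N, \lambda_i)$ and estimation
recovers $K$ on its own scale (the compositional constant is 1 by
construction). The filler row is labelled and excluded from estimation
summaries.

## Numerical choices and problem sizes

* SDE integration: Euler–Maruyama in the Itô convention; negative
  excursions clipped to $10^{-15}K$; a warning when $dt > \tau/10$;
  divergence reported with the step index. The integrator is validated by
  Kolmogorov–Smirnov agreement between its long-run marginal and the
  closed-form Gamma law.
* Reproducibility: every stochastic function takes an optional `seed` and
  runs under `withr::with_seed`, restoring the caller's RNG state; ensemble
  and fixture generators derive per-stage seeds from one master seed.
* Test problem sizes are chosen to give comfortable statistical margins at
  interactive runtimes: $10^5$ draws for distributional KS checks,
  $S = 10^4$ and 200 pairs for the calibration and DOC checks, 200–300
  timepoints at depth $5\times10^4$ for parameter recovery. The acceptance
  checks in `tests/testthat/test-acceptance.R` state their tolerances
  inline.

```{r example, eval = FALSE}
# a minimal end-to-end run
cfg <- pair_config(S = 1e4, rho_K = 0.8)
pair <- generate_pair(cfg, seed = 1)
all_metrics(sample_pair(pair$counts_A, pair$counts_B))

curve <- calibrate_rho_spearman(pair_config(rho_K = 1), seed = 1)
infer_rho_K(sample_pair(pair$counts_A, pair$counts_B), curve)
```
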