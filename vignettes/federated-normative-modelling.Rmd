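---
title: "Federated hierarchical Bayesian normative modelling: methods and design"
author: "fednorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated hierarchical Bayesian normative modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A normative model is a growth-chart for a biological measure: a regression
of a phenotype (say, regional cortical thickness) on covariates (age, sex)
that yields population centiles, so that an individual's measurement can be
expressed as a deviation z-score from the norm. Two practical obstacles
dominate multi-center applications. First, data pooled across acquisition
sites carry *site effects* — additive and multiplicative shifts induced by
scanners and pipelines — which contaminate both the estimated centiles and
the deviation scores. Second, raw subject-level data frequently cannot be
shared across centers, so the model must be estimable and updatable on
*decentralized* data, and adaptable to small local clinics that may hold a
handful of subjects — or none — per stratum.

`fednorm` addresses both with one generative model: hierarchical Bayesian
regression (HBR) with partial pooling over batches, plus two federated
mechanisms built on its generative nature (posterior-predictive data
synthesis for model extension, and informative-prior transfer for
deployment-time adaptation).

# The model

Let $y$ be one region's phenotype and $x$ age. Observed (site, sex)
combinations define batches $i = 1, \dots, m$; both site and sex are
group-effects, composed as their observed cross-product, so every batch
receives its own parameters:

$$ y \mid \text{batch } i \sim N\!\big(f_{\mu i}(x), \; f^+_{\sigma i}(x)^2\big),
\qquad f_{\mu i}(x) = \phi(x)^\top \theta_{\mu i}, $$

with $\phi(x)$ a basis expansion of age (linear, cubic polynomial, or a
cubic B-spline with five evenly spaced interior knots). Noise is either
*homoscedastic per batch*, $\sigma_i = e^{\lambda_i}$ with the log-scales
pooled hierarchically, $\lambda_i \sim N(\mu_{\theta\sigma},
\sigma_{\theta\sigma}^2)$, or *heteroscedastic*,
$f^+_{\sigma i}(x) = \log(1 + e^{\phi(x)^\top \theta_{\sigma i}})$ — the
softplus guarantees positivity.

Partial pooling ties the batches together: coefficients are exchangeable
draws from shared priors,
$\theta_{\mu i} \sim N(\mu_{\theta\mu}, \sigma_{\theta\mu}^2)$ per
coefficient, with weakly-informative hyperpriors
$\mu_{\theta\mu}, \mu_{\theta\sigma} \sim N(0, 10^3)$ (variance $10^3$) and
$\log \sigma_{\theta\mu}, \log \sigma_{\theta\sigma} \sim N(0, 2.5^2)$.
This interpolates between complete pooling (one global fit; stable but
blind to site effects) and no pooling (independent fits; flexible but
unstable on small batches): the shared prior acts as a ridge-like
regularizer learned from the data.

Deviations use the batch-specific functions,
$z = (y - f_{\mu i}(x)) / f^+_{\sigma i}(x)$, so additive and
multiplicative site effects are compensated *in the score* without ever
harmonizing the data. The abnormal probability index
$P_{abn}(z) = 2\Phi(|z|) - 1$ maps a z-score to the two-sided probability
mass within $|z|$; it is 0 at the norm and approaches 1 in either tail.

# Inference

The model is conditionally conjugate: given the scales, each batch's
coefficient vector and each hyper-mean have closed-form Gaussian
conditionals. `fednorm` therefore samples the posterior with a blocked
Gibbs sampler — exact multivariate-normal draws for the conjugate blocks,
univariate slice sampling (stepping-out with shrinkage) for the scale
parameters, and, in the heteroscedastic case, per-coordinate slice updates
of the softplus noise coefficients. Homoscedastic updates touch only
per-batch sufficient statistics ($X_i^\top X_i$, $X_i^\top y_i$,
$y_i^\top y_i$, $n_i$), so an iteration's cost is independent of the number
of subjects — the property that makes the federated extension loop, which
repeatedly refits on thousands of synthetic rows, cheap.

Centered Gibbs updates of a hierarchy's spread mix slowly when the
across-batch variance is small, so after each centered update the sampler
re-updates each $\log \sigma_{\theta\mu}[j]$ (and the noise spread) in the
*ancillary* parameterization — holding the standardized deviations
$\epsilon_{ij} = (\theta_{ij} - \mu_j)/\sigma_j$ fixed so the data inform
the scale directly. This interweaving removes the characteristic
random-walk behaviour of the spread parameters at negligible cost.

Defaults are 2 chains of 1000 warm-up and 1000 retained draws; convergence
is monitored by split R-hat on the hyperparameters with a warning attached
to the model above 1.05. A batch with no likelihood contribution (declared
but empty) is drawn from the current prior — exactly the behaviour the
few-shot machinery relies on. Design columns of the linear and polynomial
bases are standardized internally (training mean/sd) so coefficients live
on comparable scales under the shared prior; draws are mapped back to raw
units by the exact affine transform when reported. The B-spline basis is
already bounded in $[0,1]$ (it is used with its full partition-of-unity
basis, which spans constants, so no separate intercept column is added) and
is used unstandardized.

# The federated life-cycle

**Extension.** Because the model is generative, a trained model can
synthesize a faithful surrogate of its training data: for each registered
batch, ages on a grid (default 80 one-year steps from 10 to 89), 5
replicates per (age, sex) cell — 800 rows per two-sex site — each drawn
from $N(f_{\mu i}, f^{+2}_{\sigma i})$ under a randomly selected posterior
draw. Extending the model with a new site's data means refitting on
{synthetic cohort + new data}; raw prior-stage data are never touched (the
operation takes only the model object and the new dataset). Iterating adds
one decentralized dataset at a time.

**Adaptation.** For deployment, the posterior of the *hyperparameters* is
summarized as independent Gaussians (posterior mean and sd per
hyperparameter, log-space for the spreads, with a floor of $10^{-3}$ on
every prior scale so a degenerate posterior can never become dogmatic) and
shipped as a JSON payload containing no subject- or site-level information.
A local center refits the hierarchical model on its own data under this
informative hyperprior. With ample local data the prior washes out and the
fit approaches independent least squares; with one subject the slope is
held near the population value; with zero subjects the prior-mean curve is
returned. The spec records the reference model's basis, design
standardization and fit range, so the transferred prior always refers to
the same parameterization — a mismatched basis is an explicit error.

# Baselines

Four classical strategies share the same fit/predict/z-score surface:
naive pooling (one global fit), fixed-effect pooling (one-hot site
indicators as covariates; prediction at an unseen site is deliberately an
error — its deployment limitation), no pooling (independent least squares
per batch, with batches smaller than the parameter count flagged unusable),
and ComBat-then-pooling. ComBat is implemented in its standard parametric
empirical-Bayes form (normal prior on additive, inverse-gamma on squared
multiplicative effects, iterated to convergence) with an explicit
train/apply split so held-out data are harmonized with training-only
parameters; age (via the chosen basis) and sex are preserved in the design.
Baseline mean functions are least-squares fits: they are point estimates by
construction, and MCMC would buy nothing for a non-hierarchical model. Sex
enters the pooled baselines as a binary covariate (in HBR and no-pooling it
is part of the batch definition).

# Evaluation and the audit

Fit quality is scored per region on held-out data by RHO (Pearson
correlation of observation and predicted mean), SMSE (mean squared error
over test-target variance; 1 is the trivial mean predictor) and MSLL (mean
Gaussian negative log-density minus the same under the trivial
training-moments predictor; the only metric that punishes a miscalibrated
variance). The trivial predictor uses the global cross-site training
moments — per-site moments would leak exactly the site information the
models differ on. Residual site information in z-scores is quantified by
the site-leakage audit: for every site pair, a linear SVM (C = 1, 5-fold
stratified CV, no rescaling — z-scores are already on a common scale)
classifies the site label from the subjects-by-regions z-matrix and the
mean one-vs-one balanced accuracy is reported. Site pairs with fewer than
five subjects on either side are skipped with a warning rather than
producing meaningless folds.

The anomaly-detection harness scores patients against healthy by the
region-wise AUC of $P_{abn}$, assesses significance by a permutation test
(diagnosis labels shuffled at the subject level — the natural exchangeable
unit — with a two-sided p-value on $AUC - 0.5$), corrects across regions by
Benjamini–Hochberg, and reports a region only if it passes FDR in at least
9 of 10 repeated runs ("significant and stable"). AUC ties use midranks.

# The synthetic cohort generator

Real multi-site collections differ in per-site age windows, sample sizes,
acquisition effects and noise levels; the generator reproduces that
structure with known ground truth. Each site has its own age window (ages
uniform within it), size (0 and 1 allowed, to exercise the few-shot paths),
additive intercept shift, multiplicative slope scaling, noise sd,
and sex ratio; regions share a population curve (intercept, age slope, sex
offset) with defaults shaped like cortical thickness: intercepts
2.2–2.8 units, age slopes spanning 0 to −0.015 units/year so regions range
from signal-free to strongly age-dependent, sex offset 0.05, noise sds
0.10–0.18. Sex is a categorical label, not a numeric covariate, so it can
be treated as a group-effect. Patients are flagged with a configurable
probability and shifted by a per-region effect expressed in noise-sd units;
the stored ground-truth mean remains the healthy norm, so injected
deviations are visible to z-scoring. A variant generator correlates site
membership with age (site windows interpolate from identical to disjoint as
the confound strength goes 0 to 1) and plants an unlabeled binary "latent
subtype" whose prevalence varies across sites — the configuration in which
location/scale harmonization provably removes biological signal, which the
test suite demonstrates as a shrinking subtype t-statistic after ComBat.

Each site consumes an arithmetically derived substream of the master seed,
so adding a site never changes earlier sites' draws. What the generator
does *not* emulate: non-Gaussian (skewed or bounded) phenotypes,
cross-region covariance, longitudinal repeat scans, and scanner drift
within site. Tests passing on these cohorts therefore certify the
machinery under the model's own assumptions, not robustness to their
violation.

# Numerical choices and edge cases

* Out-of-range prediction ages are clamped to the training range by
  default (a B-spline basis is undefined beyond its boundary knots, and a
  flat continuation is the conservative choice for a centile chart); a
  first-order linear extension is available per basis configuration.
* "Five evenly spaced knots" is read as five *interior* knots evenly
  spaced over the observed training age range, boundary knots at the range
  ends. Quantile placement was rejected to keep knots independent of the
  site mix.
* The hyperprior variance $10^3$ is read as a variance (sd $\approx
  31.6$), and 2.5 as a standard deviation in log space; both are
  configurable per coefficient.
* Slice sampling uses width 1 (0.5 for noise parameters) with at most 50
  stepping-out moves; conjugate draws use Cholesky solves of the posterior
  precision.
* A training set with a single distinct age would make the fit range
  degenerate; it is widened by ±0.5 years.
* Ties in AUC use midranks; permutation p-values use the add-one
  (\(+1\)) convention, so zero p-values cannot occur.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run scaled-down versions of the
experimental protocols, chosen to make the qualitative contrasts decisive
while keeping a full run comfortable on one CPU: the extension-vs-
centralized comparison uses 8 sites of 150 subjects and 20 regions of
graded signal strength (R² between the per-region correlation vectors of
the extended and the centralized model is the reported statistic); the
audit uses 4 sites of 150 subjects with neighbouring-site shifts of about
two noise sds; adaptation compares 10 simulated 10-subject clinics against
no-pooling; calibration checks 95% credible-interval coverage of true
slopes over 20 simulated cohorts. These experiment fits use reduced
sampler settings (a single chain with 300 warm-up and 400 retained draws):
the conjugate blocked sampler reaches its stationary regime quickly, and
the test suite cross-checks its posterior summaries against an independent
JAGS implementation of the same model.

# Known limitations

The likelihood is Gaussian; skewed or bounded phenotypes would need a
warped or shape-parameterized likelihood, which this package deliberately
does not implement. Regions are modelled independently — multivariate site
effects in the cross-region covariance are untouched, which is also why a
multivariate classifier retains slightly-above-chance site information
even from well-behaved z-scores. Extension transports information through
synthetic cohorts, so hyperparameter uncertainty is propagated only
approximately; generating more replicates tightens it at linear cost. The
informative-prior summary drops posterior correlations between
hyperparameters (a full-covariance transfer would be a drop-in
replacement). And the audit's SVM sees only linear structure; a nonlinear
probe could leak more.
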