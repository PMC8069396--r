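---
title: "Methods: the Type I half-logistic odd Weibull-G family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Type I half-logistic odd Weibull-G family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlowg)
```

## The family

Let $G(x;\varphi)$ be any absolutely continuous baseline CDF on $(0,\infty)$
with density $g$, and let
$t(x) = G(x;\varphi)/\bar G(x;\varphi)$ be its odds ratio, a nondecreasing
map of $(0,\infty)$ onto $(0,\infty)$. The Type I half-logistic odd
Weibull-G (Type I HLOW-G) family composes two layers on top of $t$: an
odd-Weibull power layer with shape $\beta > 0$ and a half-logistic damping
layer with scale $\lambda > 0$. Writing $w = \lambda\, t(x)^\beta$,

$$F(x) = \frac{1 - e^{-w}}{1 + e^{-w}} = \tanh(w/2), \qquad
f(x) = 2\lambda\beta\, g\, G^{\beta-1}\bar G^{-(\beta+1)}
       \frac{e^{-w}}{(1+e^{-w})^2},$$

with hazard rate
$h(x) = \lambda\beta\, g\, G^{\beta-1}\bar G^{-(\beta+1)} (1+e^{-w})^{-1}$.
Depending on the baseline and on $(\lambda,\beta)$ the hazard can be
increasing, decreasing, unimodal or bathtub-shaped, which is the family's
modelling appeal for lifetime data. Six baselines are built in
(exponential, Rayleigh, Lindley, Weibull, Fréchet, Lomax); the quantile
function inverts in closed form down to the baseline,

$$Q(u) = G^{-1}\!\left(\frac{t_u}{1+t_u}\right), \qquad
t_u = \left[-\tfrac{1}{\lambda}\log\tfrac{1-u}{1+u}\right]^{1/\beta},$$

and random generation is inverse-transform only.

### Parameterization conventions

Two of the baselines admit more than one common convention, so the package
fixes them explicitly:

* **Fréchet**: $G(x) = \exp\{-(a/x)^b\}$ with $a$ the scale and $b$ the
  shape. Under this convention the fitted four-parameter model for the
  aluminum-coupon application places about half its mass below the sample
  mean of that dataset, which is the behaviour the published fits imply;
  the alternative reading ($a x^{-b}$ with $a$ a combined rate) puts
  essentially no mass there and is inconsistent with every downstream
  number.
* **Weibull**: $G(x) = 1 - \exp\{-(x/b)^a\}$, $a$ shape, $b$ scale.
* **Lindley**: the standard one-parameter form
  $G(x) = 1 - (1 + ax/(a{+}1))e^{-ax}$ is used; its quantile function has
  no elementary closed form and is inverted numerically (monotone
  bisection on the log-survival scale, tolerance $10^{-13}$).

### Numerical design

All family functions are routed through $\log t = \log G - \log \bar G$,
with both logs computed directly per baseline (for example
$\log \bar G = -ax$ for the exponential), and $w = \lambda e^{\beta \log t}$.
This matters in practice: published fits of this family reach
$\beta \approx 17$, where naive powering of the odds over- or underflows.
The CDF saturates cleanly at 1 for large $w$ while the survival function
uses the reduced form $2e^{-w}/(1+e^{-w})$, which stays accurate deep in
the right tail. The quantile layer evaluates
$-\log\{(1-u)/(1+u)\} = \log(1+u) - \log(1-u)$ in `log1p` form and
switches the baseline inversion to the survival scale whenever $t_u > 1$,
so both tails keep full relative precision.

## Distributional properties by quadrature

The family admits a formal expansion of the density as an infinite
mixture of exponentiated-G densities, obtained by interchanging three
series. The interchange is not rigorous — after reordering, the inner
alternating binomial sum $\sum_i \binom{-2}{i}(i+1)^{j+1}$ diverges
termwise — so the package does not use the mixture coefficients for any
numerical purpose. Instead:

* **Moments and their relatives** are computed in $u$-space,
  $E[X^r] = \int_0^1 Q(u)^r\,du$, by adaptive quadrature
  (`integrate`, relative tolerance $10^{-10}$, up to 1000 subdivisions),
  which avoids the infinite domain altogether. Incomplete moments,
  probability-weighted moments, Lorenz/Bonferroni ordinates, mean
  deviations and (reversed) residual-life moments are all variations on
  the same integral with modified integrands or limits.
* **Entropies** are computed in $x$-space with the support truncated at
  the $10^{-12}$ and $1-10^{-12}$ quantiles. A single integral
  $I = \int f^\rho$ feeds the Rényi, Havrda–Charvát, Arimoto and Tsallis
  entropies exactly (they are deterministic transforms of $I$); the
  Shannon entropy $-\int f \log f$ is its own integral. The Tsallis order
  $\gamma$ is identified with $\rho$ by default and exposed as an
  optional argument, since no separate value is ever specified for it in
  the source material.
* The one **convergent** series — expanding only $(1+e^{-w})^{-2}$
  binomially, which is alternating with terms decreasing in magnitude —
  is kept as `hlow_series_pdf()`, an independent oracle for the density
  whose truncation error obeys the Leibniz bound.

**Skewness and kurtosis conventions.** The standard central-moment forms
are used: $\mathrm{Sk} = \mu_3/\sigma^3$ and plain
$\mathrm{Ku} = \mu_4/\sigma^4$ (normal reference 3), with an excess
variant behind a flag. The source material prints a skewness numerator
missing the factor 2 on $\mu_1'^3$ and a kurtosis numerator in excess
form while its descriptive tables report plain kurtosis near 3–4; the
package implements the standard definitions and documents rather than
resolves that inconsistency.

**A note on the published descriptive-statistics table.** The package's
quadrature reproduces, digit for digit, the row of that table labeled
*empirical* for the first application (mean 131.277, variance 499.965,
skewness −0.5725, kurtosis 3.3745 at the published Bayes estimates),
while the row labeled *theoretical* coincides with the classic dataset's
well-known sample statistics (mean 133.73, variance ≈ 500) — the two row
labels are evidently transposed there. For the second application the
quadrature values at the published Bayes estimates
(mean 1.5218, variance 0.0780, skewness −1.2339, kurtosis 5.3093, all
confirmed independently by $x$-space survival-function integration and by
$2\times10^6$ Monte Carlo draws) match neither printed row at any of the
printed parameter sets; the printed "theoretical" row again equals the
dataset's empirical statistics. The tests and the acceptance script
report the honestly computed values.

## Estimation

### Classical

The log-likelihood, in the form consistent with the density, is

$$\ell = n\log(2\lambda) + n\log\beta + \sum\log g
 + (\beta-1)\sum\log G - (\beta+1)\sum\log\bar G
 - \lambda\sum t_i^\beta - 2\sum\log(1+e^{-\lambda t_i^\beta}),$$

(the last term appears in the source with a sign/argument typo,
$-2\sum\log(1-e^{-w})$, which would not integrate to the stated density).
The score is analytic in $(\lambda,\beta)$ for every baseline and in
$\varphi$ for the exponential and Fréchet baselines; other baselines use
central differences of $\log g, \log G, \log\bar G$ inside the same
score formulas.

The three minimum-distance objectives share one definition of the fitted
probabilities $z_j = F(x_{(j)})$ (stable sort, ranks by position under
ties): least squares $V = \sum (z_j - \tfrac{j}{n+1})^2$, weighted least
squares with weights $(n{+}1)^2(n{+}2)/\{j(n{-}j{+}1)\}$, and
Cramér–von Mises $C = \tfrac{1}{12n} + \sum (z_j - \tfrac{2j-1}{2n})^2$ —
the same $C$ the goodness-of-fit battery reports.

All objectives are minimized over $\log$-parameters (positivity without
constraints) by BFGS (with the analytic score where available) followed
by a Nelder–Mead polish, from a moment-matched start plus multi-start
jitter drawn log-uniformly over two decades either side. Two practical
safeguards, both visible in the code:

* **A compact search box** of three decades either side of the starting
  guess. The $(\lambda,\varphi)$ profile of this family is a nearly flat
  ridge ($\lambda$ and the baseline scale trade off through
  $\lambda t^\beta$), and for some small samples the objective keeps
  improving marginally along it without bound; the box makes the
  reported optimum the constrained one, and fits whose finite-difference
  gradient is not small (for example because they sit on the box edge)
  are flagged `converged = FALSE`.
* **Simulation harnesses start each replicate at the generating truth**
  (`init = truth`, single start), the standard design for recovery
  studies, so each replicate is solved by local optimization around the
  interior optimum rather than by a global search along the ridge.

Standard errors: inverse numeric Hessian at the optimum for maximum
likelihood (delta-method mapped from the log scale); nonparametric
bootstrap (default $B = 200$) for the distance estimators, whose
asymptotic variances have no convenient closed form.

### Bayesian

For the exponential $(\lambda,\beta,a)$ and Fréchet $(\lambda,\beta,a,b)$
sub-models, independent Gamma priors are placed on every parameter.
Elicitation is moment matching: prior mean equal to a supplied central
value $m$ with common variance $v$ (shape $m^2/v$, rate $m/v$); $v=0.4$
is the informative setting and $v=2.5$ the non-informative one.

The published sampler interleaves Gibbs draws from Gamma "full
conditionals" for $\lambda, \beta$ (and $b$) with a normal random-walk
Metropolis step for $a$. Two facts about those Gamma laws drive the
design here:

1. They are **not the true conditionals**: each omits likelihood factors
   that still depend on the parameter being updated (for example the
   $e^{-\lambda \sum t_i^\beta}$ factor, which depends on $\beta$, is
   absent from the $\beta$ conditional). The omissions are of leading
   order — on a synthetic $n=200$ sample at the truth, the printed
   $\beta$ law centres at 4.4 while the true conditional centres at 2.3 —
   so they are unusable even as independence proposals (measured
   acceptance below $10^{-3}$; the chain effectively freezes).
2. Their rates can be **non-positive** on real data (the $\beta$ rate is
   $d_4 - a\sum x_i - \sum\log(1-e^{-ax_i})$), making the law improper.

The default `corrected` mode therefore updates *every* parameter with
the move type the algorithm prescribes for $a$: a normal random-walk
Metropolis step targeting the exact joint posterior, with each proposal
scale adapted towards a 20–45 % acceptance rate during burn-in (window
of 50 iterations) and frozen afterwards to preserve detailed balance.
An `as_printed` mode reproduces the published scheme verbatim for
comparison — direct Gamma draws, a random-walk fallback with a warning
whenever a rate is non-positive, and an $a$-step whose acceptance ratio
uses the printed conditional density.

Point estimates follow the two loss functions: squared-error loss gives
the posterior mean; generalized entropy loss with shape $\kappa \ne 0$
gives $\{E(\psi^{-\kappa})\}^{-1/\kappa}$, recovering the squared-error
estimate at $\kappa = -1$, the precautionary-loss estimate at
$\kappa = -2$ and the entropy-loss (harmonic-mean) estimate at
$\kappa = 1$. Reported Bayes standard errors are posterior standard
deviations of the retained draws.

Convergence is monitored by the Geweke diagnostic comparing the first
10 % and last 50 % of each retained chain. The spectral density at zero
is estimated from an AR fit with AIC order selection,
$\hat S(0) = \hat\sigma^2/(1-\sum_k \hat\phi_k)^2$ — the standard
implementation of this diagnostic in R — rather than a tapered
periodogram, because the AR estimator is well defined for the short
windows the diagnostic uses and is reproducible against the reference
implementation (the test suite cross-checks it against `coda`).

## Goodness of fit

From a fitted model with $q$ free parameters on $n$ observations the
report carries $-\log L$ and the four information criteria
($\mathrm{AkIC} = 2(-\log L) + 2q$, its small-sample correction, the
Bayesian and the Hannan–Quinn criteria); the Kolmogorov–Smirnov
statistic with its asymptotic-series p-value (parameters treated as
known — the estimated-parameter caveat is documented, not corrected, to
match how such tables are conventionally produced); plain $A^2$ and
$W^2$ without small-sample modification factors (the published
Cramér–von Mises values equal the $\tfrac{1}{12n}$ form, which pins this
choice down); and the scaled total-time-on-test transform, whose
concavity diagnoses an increasing failure rate.

## The synthetic-data generator and the simulation harness

`generate_fixture()` writes inverse-transform samples plus a JSON
manifest (model, parameters, $n$, seed). Its role is to emulate the two
classic application datasets from their published fitted parameters —
101 aluminum-coupon fatigue lifetimes (Fréchet baseline) and 63
glass-fibre strengths (exponential baseline) — because the originals are
not bundled. What such fixtures reproduce is the *fitted* distributions:
they inherit none of the rounding, discreteness or mild lack-of-fit of
the real measurements, so tests built on them demonstrate internal
consistency of the machinery, not empirical adequacy of the models.

The study harness draws replicates at the truth values
$(\lambda,\beta,a) = (1.3, 2.3, 1.5)$ for the exponential sub-model and
$(1.3, 1.8, 1.5, 1.9)$ for the Fréchet sub-model, over a grid of sample
sizes (default $n = 20, 25, \dots, 150$, 1000 replicates) and reports
average bias and MSE per parameter and method, dropping and counting
failed replicates. Replicate seeds derive deterministically from the
base seed, the sample size and the replicate index, so any cell can be
reproduced bitwise. The Bayesian arm shortens the chains to
$M = 11{,}000$ draws, 1000 burn-in, thinning 10 (the full published
settings $M = 55{,}000$, burn-in 5000, thinning 10 remain available
through the chain configuration), which desk-scale experiments show is
ample for these three- and four-parameter posteriors. The test suite
exercises a reduced replication — 200 replicates at
$n \in \{20, 50, 150\}$ for the classical estimators and at $n = 50$ for
the Bayes arm, and $10^6$ draws for the quadrature-versus-Monte-Carlo
oracle checks — sizes chosen as a sensible desk-scale compromise and
stated here so they can be scaled back up.

## Known limitations

* No censoring, truncation or covariates; the likelihood is for complete
  iid positive samples.
* The KS p-value ignores parameter estimation, as discussed above.
* Maximum likelihood for this family can be genuinely ill-posed at small
  $n$ (the flat $\lambda$–$\varphi$ ridge); the box constraint makes the
  reported estimates well defined but they can sit on the box boundary,
  which the `converged` flag exposes. The Bayesian estimates do not
  suffer from this and are markedly more stable at small $n$, which is
  also the published qualitative finding.
* Bayesian estimation covers the exponential and Fréchet sub-models
  only; the other four baselines are fit classically.
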