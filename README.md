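# hlowg

Lifetime data — component failure times, material strengths, survival
durations — often show hazard rates that plain two-parameter families
cannot capture: bathtub shapes, unimodal hazards, heavy or light tails
with strong skew in either direction. A productive way to get this
flexibility is to compose a *generator* on top of a familiar baseline
distribution. `hlowg` implements one such generator, the **Type I
half-logistic odd Weibull-G (Type I HLOW-G) family**, end to end: the
distribution itself for six baselines, its distributional properties by
numerical quadrature, five estimation methods (maximum likelihood, least
squares, weighted least squares, Cramér–von Mises minimum distance, and
Bayesian MCMC under squared-error and generalized entropy losses), a
goodness-of-fit battery, and a Monte Carlo harness for comparing the
estimators. It is aimed at reliability engineers and applied
statisticians fitting flexible lifetime models to positive univariate
samples.

## The model

Let $G(x;\varphi)$ be a baseline CDF on $(0,\infty)$ with density $g$,
and $t(x) = G/(1-G)$ its odds ratio. With scale $\lambda>0$, shape
$\beta>0$ and $w = \lambda\,t(x)^\beta$,

$$F(x;\lambda,\beta,\varphi) \;=\; \frac{1-e^{-w}}{1+e^{-w}}, \qquad
f(x) \;=\; 2\lambda\beta\, g\, \frac{G^{\beta-1}}{(1-G)^{\beta+1}}\,
\frac{e^{-w}}{(1+e^{-w})^2}, \qquad x>0 .$$

The odd-Weibull layer ($t^\beta$) reshapes the tails; the half-logistic
layer damps them. Baselines: exponential, Rayleigh, Lindley, Weibull,
Fréchet (as $G=\exp\{-(a/x)^b\}$, $a$ scale, $b$ shape) and Lomax. The
quantile function is closed-form down to the baseline, so random
generation is inverse-transform and fully seeded. The two sub-models
studied in depth are the Fréchet one (four parameters
$\lambda,\beta,a,b$) and the exponential one ($\lambda,\beta,a$), the
latter with CDF $F(x) = \tanh\{\tfrac{\lambda}{2}(e^{ax}-1)^\beta\}$.

## Worked example

Simulate a glass-fibre-like strength sample from the exponential
sub-model at its published fitted parameters, refit it by maximum
likelihood, inspect the fit, and run a short Bayesian chain:

```r
library(hlowg)

p <- hlow(lambda = 0.4016, beta = 3.3597, "exponential", phi = 0.5530)
x <- rhlow(63, p, seed = 2021)

f <- hlow_fit(x, "exponential", method = "mle", starts = 10, seed = 1)
print(f)
#> Type I HLOW-exponential fit (MLE), n = 63
#>          lambda   beta       
#> estimate 0.0048 1.4998 2.2352
#> se       0.0055 1.4578 2.4426
#> objective 12.9721, converged: TRUE

hlow_gof(f$model, x)
#> -logL 12.9721  AkIC 31.9441  CAkIC 32.3509  BsIC 38.3735  HQIC 34.4729
#> AD 0.4332  CvM 0.0551  KS 0.0758 (p = 0.8623)  df 3  n 63

hlow_moments(p)
#> mean 1.50326  variance 0.0980839  skewness -0.672311  kurtosis 3.46199  IoD 0.0652474

ch <- hlow_mcmc(x, "exponential", elicit_prior(f$estimates, 2.5),
                hlow_chain_config(draws = 11000, burnin = 1000, thin = 10,
                                  seed = 1))
print(ch)
#> Posterior chain (exponential sub-model, corrected mode): 1000 retained draws
#>            lambda    beta       a
#> mean       0.0068  1.4558  2.5140
#> sd         0.0053  0.4499  0.8183
#> acceptance 0.2602  0.2541  0.3200
#> geweke_z   0.0671 -0.4897 -0.0598
```

Reading the output: the MLE lands on a different point of the
$\lambda$–$a$ ridge than the generating parameters — the three
parameters trade off strongly at $n = 63$, which the large standard
errors and the posterior spread both show, while fit quality (KS p-value
0.86) is excellent; the theoretical moments at the generating parameters
give a mildly left-skewed, strongly under-dispersed distribution
(variance/mean ≈ 0.065); and the Geweke $|z|$ values well below 1.96
indicate a converged chain with healthy 25–32 % acceptance rates.

The MLE estimates here differ from the generating values while fitting
the sample extremely well — the family's likelihood surface has a flat
ridge, discussed in the methods vignette
(`vignettes/hlowg-methods.Rmd`), which is exactly why the Bayesian
estimates with their ridge-regularizing priors are the more stable
choice at small $n$.

A command-line front end wraps the same functionality:

```sh
exec/hlowg rvs --baseline exponential --params 1.3,2.3,1.5 -n 100 --seed 7 -o sample.txt
exec/hlowg fit --data sample.txt --baseline exponential --method mle --out report.json
exec/hlowg properties --baseline frechet --params 0.4696,17.1055,27.7908,0.2562
```

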