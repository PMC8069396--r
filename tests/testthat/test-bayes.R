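test_that("prior elicitation inverts the Gamma mean/variance relations", {
  pr <- elicit_prior(c(1.3, 2.3, 1.5), 0.4)
  expect_equal(pr$shape[1], 1.3^2 / 0.4, tolerance = 1e-12)  # 4.225
  expect_equal(pr$rate[1], 1.3 / 0.4, tolerance = 1e-12)     # 3.25
  prn <- elicit_prior(1.3, 2.5)
  expect_equal(prn$shape, 0.676, tolerance = 1e-12)
  expect_equal(prn$rate, 0.52, tolerance = 1e-12)
  expect_equal(pr$shape / pr$rate, c(1.3, 2.3, 1.5), tolerance = 1e-12)
  expect_error(elicit_prior(c(-1, 2), 0.4), "positive")
  expect_error(elicit_prior(1, -2), "positive")
})

test_that("the log posterior is likelihood plus Gamma kernels", {
  p <- hlow(1.3, 2.3, "exponential", phi = 1.5)
  x <- rhlow(120, p, seed = 41)
  pr <- elicit_prior(c(1.3, 2.3, 1.5), 0.4)
  for (th in list(c(1.3, 2.3, 1.5), c(0.7, 1.1, 2.2))) {
    manual <- -hlow_nll(theta_to_hlow_test("exponential", th), x) +
      sum((pr$shape - 1) * log(th) - pr$rate * th)
    expect_equal(hlow_log_posterior("exponential", th, pr, x), manual,
                 tolerance = 1e-10)
  }
  expect_identical(hlow_log_posterior("exponential", c(-1, 2, 1), pr, x), -Inf)
  # Frechet model too
  pf <- hlow(1.3, 1.8, "frechet", phi = c(1.5, 1.9))
  xf <- rhlow(80, pf, seed = 42)
  prf <- elicit_prior(c(1.3, 1.8, 1.5, 1.9), 0.4)
  thf <- c(1.1, 1.6, 1.4, 2.1)
  manual <- -hlow_nll(theta_to_hlow_test("frechet", thf), xf) +
    sum((prf$shape - 1) * log(thf) - prf$rate * thf)
  expect_equal(hlow_log_posterior("frechet", thf, prf, xf), manual,
               tolerance = 1e-10)
})

test_that("near-flat priors put the posterior mode at the MLE", {
  p <- hlow(1.3, 2.3, "exponential", phi = 1.5)
  x <- rhlow(400, p, seed = 43)
  mle <- suppressWarnings(hlow_fit(x, "exponential", method = "mle",
                                   starts = 5, seed = 1, boot = 0))
  pr <- elicit_prior(c(1, 1, 1), 1e6)
  at_mle <- hlow_log_posterior("exponential", mle$estimates, pr, x)
  for (bump in list(c(1.1, 1, 1), c(1, 1.05, 1), c(1, 1, 1.05)))
    expect_gt(at_mle,
              hlow_log_posterior("exponential", mle$estimates * bump, pr, x))
})

test_that("Bayes point estimates obey the loss-function identities", {
  draws <- cbind(theta = c(1, 2, 3, 4))
  expect_equal(as.numeric(bayes_estimate(draws, "sel")), 2.5)
  expect_equal(as.numeric(bayes_estimate(draws, "gel", kappa = -2)),
               sqrt(7.5), tolerance = 1e-12)          # precautionary loss
  expect_equal(as.numeric(bayes_estimate(draws, "gel", kappa = 1)),
               1.92, tolerance = 1e-12)               # entropy loss
  # GEL with kappa = -1 is exactly SEL
  set.seed(5); chain <- cbind(a = rgamma(500, 3, 2), b = rgamma(500, 2, 1))
  expect_equal(as.numeric(bayes_estimate(chain, "gel", kappa = -1)),
               as.numeric(bayes_estimate(chain, "sel")), tolerance = 1e-12)
  # power-mean ordering PL >= SEL >= EL
  pl <- bayes_estimate(chain, "gel", kappa = -2)
  sel <- bayes_estimate(chain, "sel")
  el <- bayes_estimate(chain, "gel", kappa = 1)
  expect_true(all(pl >= sel & sel >= el))
  expect_error(bayes_estimate(chain, "gel", kappa = 0), "kappa")
  expect_error(bayes_estimate(chain - 10, "gel", kappa = 1), "positive")
})

test_that("the sampler is deterministic and honors the burn-in/thinning contract", {
  p <- hlow(1.3, 2.3, "exponential", phi = 1.5)
  x <- rhlow(30, p, seed = 44)
  pr <- elicit_prior(c(1.3, 2.3, 1.5), 0.4)
  cfg <- hlow_chain_config(draws = 55000, burnin = 5000, thin = 10, seed = 9)
  ch <- hlow_mcmc(x, "exponential", pr, cfg)
  expect_identical(nrow(ch$draws), 5000L)
  expect_true(all(ch$acceptance >= 0 & ch$acceptance <= 1))
  ch2 <- hlow_mcmc(x, "exponential", pr, cfg)
  expect_identical(ch$draws, ch2$draws)
  expect_error(hlow_chain_config(draws = 100, burnin = 200), "draws > burnin")
})

test_that("corrected chains recover the truth under informative priors", {
  p <- hlow(1.3, 2.3, "exponential", phi = 1.5)
  x <- rhlow(200, p, seed = 11)
  pr <- elicit_prior(c(1.3, 2.3, 1.5), 0.4)
  ch <- hlow_mcmc(x, "exponential", pr, hlow_chain_config(seed = 5))
  truth <- c(1.3, 2.3, 1.5)
  for (k in 1:3)
    expect_lt(abs(ch$posterior_mean[k] - truth[k]), 3 * ch$posterior_sd[k],
              label = paste("posterior recovery", colnames(ch$draws)[k]))
  expect_true(all(abs(ch$geweke_z) < 1.96))
})

test_that("printed-conditional mode guards its improper Gamma rates", {
  # large observations make the printed beta rate d4 - a sum(x) - sum(log G)
  # negative, triggering the guarded random-walk fallback
  set.seed(46)
  x <- runif(50, 2, 5)
  pr <- elicit_prior(c(1, 1, 1.5), 0.4)
  expect_warning(
    hlow_mcmc(x, "exponential", pr,
              hlow_chain_config(draws = 600, burnin = 100, thin = 1,
                                seed = 3, mode = "as_printed")),
    "non-positive rate")
})

test_that("the Geweke diagnostic matches its null, detects trends, and agrees with coda", {
  set.seed(47)
  z <- vapply(1:100, function(i) geweke_z(rnorm(5000)), numeric(1))
  expect_gte(mean(abs(z) < 1.96), 0.90)
  trended <- rnorm(5000) + seq(0, 1, length.out = 5000)
  expect_gt(abs(geweke_z(trended)), 1.96)
  expect_error(geweke_z(rnorm(5000), first = 0.6, last = 0.5), "first \\+ last")
  expect_error(geweke_z(rnorm(50)), "too short")
  expect_error(geweke_z(rep(1, 5000)), "degenerate")
  # independent implementation check
  w <- rnorm(4000) + 0.3 * sin(seq_len(4000) / 50)
  expect_equal(geweke_z(w), unname(coda::geweke.diag(coda::mcmc(w))$z),
               tolerance = 0.15)
})

test_that("prior pull weakens as the prior flattens", {
  # the likelihood surface has a flat lambda-a ridge, so posterior MEANS
  # need not sit near the MLE; what flattening the prior must do is
  # release the pull towards the prior's own center
  p <- hlow(1.3, 2.3, "exponential", phi = 1.5)
  x <- rhlow(300, p, seed = 48)
  center <- c(3, 1, 3)
  cfg <- hlow_chain_config(draws = 21000, burnin = 1000, thin = 4, seed = 12)
  ch_tight <- hlow_mcmc(x, "exponential", elicit_prior(center, 0.05), cfg)
  ch_flat <- hlow_mcmc(x, "exponential", elicit_prior(center, 50), cfg)
  d_tight <- sum(abs(ch_tight$posterior_mean - center) / center)
  d_flat <- sum(abs(ch_flat$posterior_mean - center) / center)
  expect_lt(d_tight, d_flat)
})
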