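test_that("moment machinery satisfies its reduction identities", {
  p <- hlow(1.3, 2.3, "exponential", phi = 1.5)
  expect_equal(as.numeric(hlow_moment(p, 0)), 1)
  # PWM reductions: s = 0 gives the raw moment, r = 0 gives 1/(s+1)
  for (r in 1:3)
    expect_equal(hlow_pwm(p, r, 0), as.numeric(hlow_moment(p, r)),
                 tolerance = 1e-8)
  for (s in 0:3)
    expect_equal(hlow_pwm(p, 0, s), 1 / (s + 1), tolerance = 1e-8)
  # MGF at zero and its derivative
  expect_equal(hlow_mgf(p, 0), 1, tolerance = 1e-9)
  h <- 1e-4
  expect_equal((hlow_mgf(p, h) - hlow_mgf(p, -h)) / (2 * h),
               as.numeric(hlow_moment(p, 1)), tolerance = 1e-3)
  # moment report internal identities
  m <- hlow_moments(p)
  expect_equal(m$index_of_dispersion, m$variance / m$mean, tolerance = 1e-14)
  expect_gte(m$variance, 0)
  expect_equal(hlow_moments(p, excess = TRUE)$kurtosis, m$kurtosis - 3,
               tolerance = 1e-12)
})

test_that("incomplete moments interpolate between zero and the full moment", {
  p <- hlow(0.8, 1.6, "weibull", phi = c(1.4, 1.1))
  mu <- as.numeric(hlow_moment(p, 1))
  expect_equal(hlow_incomplete_moment(p, 1, qhlow(0.999999, p)), mu,
               tolerance = 1e-4)
  expect_lt(hlow_incomplete_moment(p, 1, qhlow(1e-8, p)), 1e-6)
  ts <- qhlow(c(0.2, 0.4, 0.6, 0.8), p)
  eta <- vapply(ts, function(t) hlow_incomplete_moment(p, 1, t), numeric(1))
  expect_true(all(diff(eta) > 0))
  expect_error(hlow_incomplete_moment(p, 0, 1), "positive integer")
})

test_that("mean deviations match the brute-force absolute-moment integral", {
  set.seed(12)
  params <- random_hlow_params(8, seed = 551)
  for (p in params) {
    md <- hlow_mean_deviations(p)
    expect_true(all(md >= 0), label = p$baseline$name)
    expect_lte(md["median"], md["mean"] + 1e-8)
  }
  # direct oracle on one model: integral of |x - mu| f(x) dx
  p <- hlow(1.1, 1.7, "exponential", phi = 0.9)
  mu <- as.numeric(hlow_moment(p, 1))
  brute <- integrate(function(x) abs(x - mu) * dhlow(x, p), 0, Inf,
                     rel.tol = 1e-10)$value
  expect_equal(as.numeric(hlow_mean_deviations(p)["mean"]), brute,
               tolerance = 1e-6)
})

test_that("Lorenz and Bonferroni curves behave like Lorenz curves", {
  p <- hlow(1.2, 1.9, "exponential", phi = 1.2)
  prob <- seq(0.05, 0.95, by = 0.1)
  bl <- hlow_bonferroni_lorenz(p, prob)
  expect_true(all(bl[, "lorenz"] <= prob + 1e-10))
  expect_true(all(diff(bl[, "lorenz"]) > 0))
  expect_equal(hlow_bonferroni_lorenz(p, 1 - 1e-9)[, "lorenz"],
               c(lorenz = 1), tolerance = 1e-4)
})

test_that("residual-life moments hit their boundary identities", {
  p <- hlow(1.4, 1.3, "rayleigh", phi = 0.8)
  mu <- as.numeric(hlow_moment(p, 1))
  # mean residual life at x is mu - x as x -> 0
  x0 <- qhlow(1e-9, p)
  expect_equal(hlow_residual_moment(p, 1, x0), mu - x0, tolerance = 1e-6)
  med <- qhlow(0.5, p)
  rev <- hlow_residual_moment(p, 1, med, reversed = TRUE)
  expect_gt(rev, 0); expect_lt(rev, med)
  expect_error(hlow_residual_moment(p, 1, 1e308), "condition")
})

test_that("the four entropy transforms share one integral and meet the Shannon limit", {
  p <- hlow(1.3, 2.3, "exponential", phi = 1.5)
  e <- hlow_entropy(p, rho = 1.7)
  I <- e$integral_I
  expect_equal(e$renyi, log(I) / (1 - 1.7), tolerance = 1e-14)
  expect_equal(e$havrda_charvat, (I - 1) / (2^(1 - 1.7) - 1), tolerance = 1e-14)
  expect_equal(e$arimoto, 1.7 / (1 - 1.7) * (I^(1 / 1.7) - 1), tolerance = 1e-14)
  expect_equal(e$tsallis, (1 - I) / (1.7 - 1), tolerance = 1e-14)
  # Renyi tends to Shannon as rho -> 1
  e1 <- hlow_entropy(p, rho = 1.001)
  expect_equal(e1$renyi, e1$shannon, tolerance = 1e-2)
  expect_error(hlow_entropy(p, rho = 1), "rho")
})

test_that("order-statistic densities reduce, normalize and match simulation", {
  p <- hlow(1.2, 1.8, "exponential", phi = 1.1)
  x <- c(0.3, 0.7, 1.2)
  expect_equal(hlow_order_stat_pdf(p, 1, 1, x), dhlow(x, p), tolerance = 1e-12)
  expect_error(hlow_order_stat_pdf(p, 5, 6, 1), "rank")
  expect_equal(integrate(function(y) hlow_order_stat_pdf(p, 5, 3, y),
                         0, Inf, rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  # medians of five against the implied order-statistic law
  meds <- apply(matrix(rhlow(5e4 * 5, p, seed = 88), ncol = 5), 1,
                stats::median)
  ks <- suppressWarnings(
    stats::ks.test(meds, function(q) stats::pbeta(phlow(q, p), 3, 3)))
  expect_gt(ks$p.value, 0.01)
})

test_that("the binomial series expansion converges to the density with the Leibniz bound", {
  p <- hlow(0.5, 0.8, "exponential", phi = 1)
  expect_equal(hlow_series_pdf(p, 1, 200), dhlow(1, p), tolerance = 1e-10)
  # single-term truncation equals the leading closed form
  bl <- p$baseline
  w <- p$lambda * exp(p$beta * (bl$logG(1) - bl$logS(1)))
  lead1 <- 2 * p$lambda * p$beta * exp(bl$logg(1) +
    (p$beta - 1) * bl$logG(1) - (p$beta + 1) * bl$logS(1)) * exp(-w)
  expect_equal(hlow_series_pdf(p, 1, 1), lead1, tolerance = 1e-12)
  # alternating-series error bound, checked on a grid
  xg <- c(0.2, 0.5, 1, 1.5)
  for (terms in c(3, 6, 12)) {
    approx <- hlow_series_pdf(p, xg, terms)
    wg <- p$lambda * exp(p$beta * (bl$logG(xg) - bl$logS(xg)))
    lead <- 2 * p$lambda * p$beta * exp(bl$logg(xg) +
      (p$beta - 1) * bl$logG(xg) - (p$beta + 1) * bl$logS(xg))
    first_omitted <- lead * (terms + 1) * exp(-(terms + 1) * wg)
    expect_true(all(abs(approx - dhlow(xg, p)) <= first_omitted + 1e-15),
                label = paste("Leibniz bound at", terms, "terms"))
  }
})

test_that("quantile-based shape measures match an independent bisection inverse", {
  p <- hlow(1.3, 2.3, "exponential", phi = 1.5)
  qs <- hlow_quantile_shape(p)
  expect_gt(qs["skewness"], -1); expect_lt(qs["skewness"], 1)
  # independent inverse of the cdf by bisection
  bis <- function(u) uniroot(function(x) phlow(x, p) - u, c(1e-12, 50),
                             tol = 1e-12)$root
  q8 <- vapply((1:7) / 8, bis, numeric(1))
  expect_equal(as.numeric(qs["skewness"]),
               (q8[6] + q8[2] - 2 * q8[4]) / (q8[6] - q8[2]), tolerance = 1e-7)
  expect_equal(as.numeric(qs["kurtosis"]),
               (q8[7] - q8[5] + q8[3] - q8[1]) / (q8[6] - q8[2]), tolerance = 1e-7)
  # a symmetric reference pushed through the same formula gives zero
  qn <- qnorm((1:7) / 8)
  expect_equal((qn[6] + qn[2] - 2 * qn[4]) / (qn[6] - qn[2]), 0,
               tolerance = 1e-12)
})

test_that("quadrature properties agree with seeded Monte Carlo oracles", {
  configs <- list(
    list(p = hlow(1, 1, "exponential", phi = 1), seed = 411),
    list(p = hlow(1.3, 1.8, "frechet", phi = c(1.5, 1.9)), seed = 412))
  for (cf in configs) {
    p <- cf$p
    x <- rhlow(1e6, p, seed = cf$seed)
    lbl <- p$baseline$name
    raw <- vapply(1:4, function(r) as.numeric(hlow_moment(p, r)), numeric(1))
    mu <- raw[1]
    expect_within_3se(x, mu, paste(lbl, "mean"))
    expect_within_3se((x - mu)^2, raw[2] - 2 * mu * raw[1] + mu^2,
                      paste(lbl, "2nd central"))
    expect_within_3se((x - mu)^3, raw[3] - 3 * raw[2] * mu + 2 * mu^3,
                      paste(lbl, "3rd central"))
    expect_within_3se((x - mu)^4,
                      raw[4] - 4 * raw[3] * mu + 6 * raw[2] * mu^2 - 3 * mu^4,
                      paste(lbl, "4th central"))
    expect_within_3se(exp(0.3 * x), hlow_mgf(p, 0.3), paste(lbl, "MGF"))
    med <- qhlow(0.5, p)
    expect_within_3se(x * (x <= med), hlow_incomplete_moment(p, 1, med),
                      paste(lbl, "incomplete moment"))
    expect_within_3se(x * phlow(x, p), hlow_pwm(p, 1, 1), paste(lbl, "PWM"))
    expect_within_3se(-dhlow(x, p, log = TRUE),
                      hlow_entropy(p, 1.5)$shannon, paste(lbl, "Shannon"))
    tail_x <- x[x > med] - med
    se <- stats::sd(tail_x) / sqrt(length(tail_x))
    expect_lt(abs(mean(tail_x) - hlow_residual_moment(p, 1, med)), 3 * se,
              label = paste(lbl, "mean residual life"))
  }
})

test_that("dispersion labels for the two fitted applications are reproduced", {
  iod_fr <- hlow_moments(hlow(0.4696, 17.1055, "frechet",
                              phi = c(27.7908, 0.2562)))$index_of_dispersion
  iod_ex <- hlow_moments(hlow(0.0019, 0.9711, "exponential",
                              phi = 4.1595))$index_of_dispersion
  expect_gt(iod_fr, 1)   # over-dispersed fit
  expect_lt(iod_ex, 1)   # under-dispersed fit
})
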