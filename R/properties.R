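# Distributional properties, all by direct numerical quadrature. Moments
# and their relatives integrate the quantile function over (0, 1), which
# sidesteps the infinite domain; entropies integrate the density in
# x-space between extreme quantiles. The family's series representation as
# an infinite Exp-G mixture is not used: the inner binomial sum diverges
# termwise after the summation interchange, so only the convergent
# single-index expansion (binomial_expansion_pdf) is retained, as an
# oracle for the density.

.hlow_quad <- function(f, lower, upper, rel.tol = 1e-10) {
  stats::integrate(f, lower, upper, rel.tol = rel.tol,
                   subdivisions = 1000L, stop.on.error = TRUE)
}

#' Raw moment by quadrature
#'
#' Computes `E[X^r] = integral of Q(u)^r over (0,1)` where `Q` is the
#' family quantile function.
#'
#' @param p an object from [hlow()].
#' @param r nonnegative integer moment order.
#' @return the moment, with the quadrature's absolute error estimate
#'   attached as attribute `"abs.error"`.
#' @export
hlow_moment <- function(p, r) {
  stopifnot(inherits(p, "hlow"), r >= 0)
  if (r == 0) return(structure(1, abs.error = 0))
  # crude divergence screen: the integrand must stay finite near u = 1
  probe <- qhlow(1 - 1e-12, p)^r
  if (!is.finite(probe))
    stop("moment of order ", r, " appears infinite", call. = FALSE)
  q <- tryCatch(.hlow_quad(function(u) qhlow(u, p)^r, 0, 1),
                error = function(e)
                  stop("moment quadrature failed: ", conditionMessage(e),
                       call. = FALSE))
  structure(q$value, abs.error = q$abs.error)
}

#' Central measures of a Type I HLOW-G distribution
#'
#' Raw moments up to order `R`, the mean, variance, skewness
#' (`mu3 / sigma^3`), kurtosis (`mu4 / sigma^4`, so the normal reference
#' is 3; set `excess = TRUE` to subtract 3) and the index of dispersion
#' (variance/mean).
#'
#' @param p an object from [hlow()].
#' @param R highest raw moment order (at least 4).
#' @param excess report excess kurtosis instead of plain kurtosis.
#' @return a list of class `"hlow_moments"` with elements `raw`, `mean`,
#'   `variance`, `skewness`, `kurtosis`, `index_of_dispersion` and
#'   `abs.error` (per raw moment).
#' @export
hlow_moments <- function(p, R = 4, excess = FALSE) {
  stopifnot(R >= 4)
  mom <- lapply(seq_len(R), function(r) hlow_moment(p, r))
  raw <- vapply(mom, as.numeric, numeric(1))
  err <- vapply(mom, function(m) attr(m, "abs.error"), numeric(1))
  m1 <- raw[1]
  v <- raw[2] - m1^2
  sk <- (raw[3] - 3 * raw[2] * m1 + 2 * m1^3) / v^1.5
  ku <- (raw[4] - 4 * raw[3] * m1 + 6 * raw[2] * m1^2 - 3 * m1^4) / v^2
  structure(list(raw = raw, mean = m1, variance = v, skewness = sk,
                 kurtosis = if (excess) ku - 3 else ku,
                 index_of_dispersion = v / m1, abs.error = err),
            class = "hlow_moments")
}

#' @export
print.hlow_moments <- function(x, ...) {
  cat(sprintf("mean %.6g  variance %.6g  skewness %.6g  kurtosis %.6g  IoD %.6g\n",
              x$mean, x$variance, x$skewness, x$kurtosis,
              x$index_of_dispersion))
  invisible(x)
}

#' Quantile-based shape measures
#'
#' Kenney-Keeping skewness
#' `(Q(3/4) + Q(1/4) - 2 Q(1/2)) / (Q(3/4) - Q(1/4))` and Moors kurtosis
#' `(Q(7/8) - Q(5/8) + Q(3/8) - Q(1/8)) / (Q(6/8) - Q(2/8))`; both exist
#' even when the distribution has no moments.
#'
#' @param p an object from [hlow()].
#' @return named vector `c(skewness =, kurtosis =)`.
#' @export
hlow_quantile_shape <- function(p) {
  q <- qhlow(c(1, 2, 3, 4, 5, 6, 7) / 8, p)
  c(skewness = (q[6] + q[2] - 2 * q[4]) / (q[6] - q[2]),
    kurtosis = (q[7] - q[5] + q[3] - q[1]) / (q[6] - q[2]))
}

#' Moment generating function by quadrature
#'
#' `E[exp(tX)] = integral of exp(t Q(u)) du` over (0, 1).
#'
#' @param p an object from [hlow()].
#' @param t numeric argument of the MGF.
#' @return the MGF value; errors if the integrand diverges near `u = 1`.
#' @export
hlow_mgf <- function(p, t) {
  stopifnot(inherits(p, "hlow"))
  probe <- exp(t * qhlow(1 - 1e-12, p))
  if (!is.finite(probe))
    stop("MGF does not exist at t = ", t, call. = FALSE)
  .hlow_quad(function(u) exp(t * qhlow(u, p)), 0, 1)$value
}

#' Incomplete moment
#'
#' `eta_s(t) = integral of x^s f(x) dx over (0, t]`, computed in u-space
#' as the integral of `Q(u)^s` over `(0, F(t))`.
#'
#' @param p an object from [hlow()].
#' @param s positive integer moment order.
#' @param t positive truncation point.
#' @export
hlow_incomplete_moment <- function(p, s, t) {
  stopifnot(inherits(p, "hlow"), t > 0)
  if (s < 1) stop("s must be a positive integer", call. = FALSE)
  Ft <- phlow(t, p)
  if (Ft == 0) return(0)
  .hlow_quad(function(u) qhlow(u, p)^s, 0, Ft)$value
}

#' Mean deviations about the mean and the median
#'
#' `delta_mean = 2 mu F(mu) - 2 eta_1(mu)` and
#' `delta_median = mu - 2 eta_1(Q(1/2))`.
#'
#' @param p an object from [hlow()].
#' @return named vector `c(mean =, median =)`.
#' @export
hlow_mean_deviations <- function(p) {
  mu <- hlow_moment(p, 1)
  med <- qhlow(0.5, p)
  c(mean = 2 * mu * phlow(mu, p) - 2 * hlow_incomplete_moment(p, 1, mu),
    median = mu - 2 * hlow_incomplete_moment(p, 1, med))
}

#' Bonferroni and Lorenz curve ordinates
#'
#' With `q = Q(prob)`, `L(prob) = eta_1(q) / mu` and
#' `B(prob) = L(prob) / prob`.
#'
#' @param p an object from [hlow()].
#' @param prob probability in (0, 1); vectorized.
#' @return matrix with columns `bonferroni` and `lorenz`.
#' @export
hlow_bonferroni_lorenz <- function(p, prob) {
  stopifnot(all(prob > 0 & prob < 1))
  mu <- hlow_moment(p, 1)
  L <- vapply(prob, function(pr)
    hlow_incomplete_moment(p, 1, qhlow(pr, p)) / mu, numeric(1))
  cbind(bonferroni = L / prob, lorenz = L)
}

#' Probability weighted moment
#'
#' `Xi(r, s) = E[X^r F(X)^s] = integral of Q(u)^r u^s du` over (0, 1).
#'
#' @param p an object from [hlow()].
#' @param r,s nonnegative integer orders.
#' @export
hlow_pwm <- function(p, r, s) {
  stopifnot(r >= 0, s >= 0)
  .hlow_quad(function(u) qhlow(u, p)^r * u^s, 0, 1)$value
}

#' Moments of (reversed) residual lifetime
#'
#' Forward: `E[(X - x)^r | X > x]`; reversed (inactivity time):
#' `E[(x - X)^r | X <= x]`. Both are computed in u-space over the
#' conditioning region.
#'
#' @param p an object from [hlow()].
#' @param r positive integer order.
#' @param x positive conditioning time with `0 < F(x) < 1`.
#' @param reversed compute the reversed residual-life moment.
#' @export
hlow_residual_moment <- function(p, r, x, reversed = FALSE) {
  stopifnot(r >= 1, x > 0)
  Fx <- phlow(x, p)
  if (Fx <= 0 || Fx >= 1)
    stop("cdf(x) is numerically 0 or 1; cannot condition", call. = FALSE)
  if (reversed) {
    .hlow_quad(function(u) (x - qhlow(u, p))^r, 0, Fx)$value / Fx
  } else {
    .hlow_quad(function(u) (qhlow(u, p) - x)^r, Fx, 1)$value / shlow(x, p)
  }
}

#' Entropies of order rho
#'
#' Computes `I = integral of f(x)^rho dx` once (the support truncated at
#' the `1e-12` and `1 - 1e-12` quantiles) and derives the Renyi
#' (`log(I)/(1-rho)`), Havrda-Charvat (`(I-1)/(2^(1-rho)-1)`), Arimoto
#' (`rho/(1-rho) (I^(1/rho)-1)`) and Tsallis (`(1-I)/(gamma-1)`)
#' entropies from it; the Shannon entropy `-E[log f]` is a separate
#' integral.
#'
#' @param p an object from [hlow()].
#' @param rho entropy order, positive and different from 1.
#' @param gamma Tsallis order; defaults to `rho`.
#' @return list of class `"hlow_entropy"` with fields `rho`, `integral_I`,
#'   `renyi`, `shannon`, `havrda_charvat`, `arimoto`, `tsallis`.
#' @export
hlow_entropy <- function(p, rho, gamma = rho) {
  stopifnot(inherits(p, "hlow"))
  if (rho <= 0 || rho == 1) stop("rho must be > 0 and != 1", call. = FALSE)
  lo <- qhlow(1e-12, p); hi <- qhlow(1 - 1e-12, p)
  I <- .hlow_quad(function(x) exp(rho * dhlow(x, p, log = TRUE)), lo, hi,
                  rel.tol = 1e-9)$value
  sh <- .hlow_quad(function(x) {
    lf <- dhlow(x, p, log = TRUE); -exp(lf) * lf
  }, lo, hi, rel.tol = 1e-9)$value
  structure(list(rho = rho, integral_I = I,
                 renyi = log(I) / (1 - rho),
                 shannon = sh,
                 havrda_charvat = (I - 1) / (2^(1 - rho) - 1),
                 arimoto = rho / (1 - rho) * (I^(1 / rho) - 1),
                 tsallis = (1 - I) / (gamma - 1)),
            class = "hlow_entropy")
}

#' @export
print.hlow_entropy <- function(x, ...) {
  cat(sprintf("order rho = %g\n", x$rho))
  cat(sprintf("  Renyi %.6g  Shannon %.6g  Havrda-Charvat %.6g  Arimoto %.6g  Tsallis %.6g\n",
              x$renyi, x$shannon, x$havrda_charvat, x$arimoto, x$tsallis))
  invisible(x)
}

#' Density of the i-th order statistic
#'
#' `f_{i:n}(x) = n!/((i-1)!(n-i)!) f(x) F(x)^(i-1) (1-F(x))^(n-i)`,
#' evaluated in log space.
#'
#' @param p an object from [hlow()].
#' @param n sample size.
#' @param i rank, `1 <= i <= n`.
#' @param x positive numeric vector.
#' @export
hlow_order_stat_pdf <- function(p, n, i, x) {
  if (i < 1 || i > n) stop("rank i must satisfy 1 <= i <= n", call. = FALSE)
  lF <- phlow(x, p, log.p = TRUE)
  lS <- shlow(x, p, log.p = TRUE)
  # n!/((i-1)!(n-i)!) = 1/B(i, n-i+1)
  exp(-lbeta(i, n - i + 1) + dhlow(x, p, log = TRUE) +
      (i - 1) * lF + (n - i) * lS)
}

#' Truncated binomial-series density
#'
#' The convergent single-index expansion of the density: expanding
#' `(1 + exp(-w))^(-2)` binomially gives
#' `f(x) = 2 lambda beta g G^(beta-1) (1-G)^(-(beta+1))
#'  sum_i choose(-2, i) exp(-lambda (i+1) t^beta)`, an alternating series
#' whose truncation error is bounded by the first omitted term. Retained
#' as an independent oracle for [dhlow()].
#'
#' @param p an object from [hlow()].
#' @param x positive numeric vector.
#' @param terms number of series terms (at least 1).
#' @export
hlow_series_pdf <- function(p, x, terms) {
  stopifnot(terms >= 1)
  bl <- p$baseline
  w <- .hlow_w(p, x)
  lead <- exp(log(2 * p$lambda) + log(p$beta) + bl$logg(x) +
              (p$beta - 1) * bl$logG(x) - (p$beta + 1) * bl$logS(x))
  i <- seq_len(terms) - 1
  # choose(-2, i) = (-1)^i (i + 1)
  s <- vapply(seq_along(x), function(k)
    sum((-1)^i * (i + 1) * exp(-(i + 1) * w[k])), numeric(1))
  lead * s
}
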