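# The Type I half-logistic odd Weibull-G family. With t(x) = G(x)/(1-G(x))
# the baseline odds and w = lambda * t^beta, the CDF is
#   F(x) = (1 - exp(-w)) / (1 + exp(-w)) = tanh(w/2).
# Everything is routed through log t = log G - log(1-G) and
# w = lambda * exp(beta * log t); fitted shapes like beta ~ 17 make naive
# powering overflow, so the cdf saturates at 1 for large w while the
# survival function keeps its algebraically reduced form 2 e^{-w}/(1+e^{-w}).

#' Type I HLOW-G parameter object
#'
#' Binds the family parameters (`lambda` scale of the half-logistic layer,
#' `beta` shape of the odd-Weibull layer) to a baseline distribution.
#'
#' @param lambda positive scale parameter of the half-logistic layer.
#' @param beta positive shape parameter of the odd-Weibull layer.
#' @param baseline an object from [make_baseline()], or a baseline name
#'   (in which case `phi` must be supplied).
#' @param phi baseline parameter vector, used when `baseline` is a name.
#' @return an object of class `"hlow"`.
#' @examples
#' p <- hlow(1, 1, "exponential", phi = 1)
#' phlow(1, p)
#' @export
hlow <- function(lambda, beta, baseline, phi = NULL) {
  if (is.character(baseline)) baseline <- make_baseline(baseline, phi)
  stopifnot(inherits(baseline, "hlow_baseline"))
  lambda <- unname(lambda); beta <- unname(beta)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(lambda = lambda, beta = beta, baseline = baseline),
            class = "hlow")
}

#' @export
print.hlow <- function(x, ...) {
  cat(sprintf("Type I HLOW-%s distribution\n", x$baseline$name))
  cat(sprintf("  lambda = %g, beta = %g, %s\n", x$lambda, x$beta,
              paste(sprintf("%s = %g", x$baseline$param_names,
                            x$baseline$phi), collapse = ", ")))
  invisible(x)
}

# w = lambda * t^beta on the log-t route; vectorized over x
.hlow_w <- function(p, x) {
  logt <- baseline_log_odds(p$baseline, x)
  p$lambda * exp(p$beta * logt)
}

#' Distribution function of the Type I HLOW-G family
#'
#' @param x nonnegative numeric vector of quantiles.
#' @param p an object from [hlow()].
#' @param lower.tail if `FALSE`, the survival function is returned using
#'   its reduced form `2 exp(-w)/(1 + exp(-w))`, which stays accurate deep
#'   in the right tail.
#' @param log.p return the log of the probability.
#' @return numeric vector of probabilities.
#' @export
phlow <- function(x, p, lower.tail = TRUE, log.p = FALSE) {
  stopifnot(inherits(p, "hlow"))
  if (any(x < 0)) stop("x must be nonnegative", call. = FALSE)
  w <- .hlow_w(p, x)
  if (lower.tail) {
    out <- -expm1(-w) / (1 + exp(-w))   # tanh(w/2); saturates cleanly at 1
    if (log.p) log(out) else out
  } else {
    lsf <- log(2) + stats::plogis(-w, log.p = TRUE)
    if (log.p) lsf else exp(lsf)
  }
}

#' Survival function of the Type I HLOW-G family
#'
#' @inheritParams phlow
#' @export
shlow <- function(x, p, log.p = FALSE) {
  phlow(x, p, lower.tail = FALSE, log.p = log.p)
}

#' Density of the Type I HLOW-G family
#'
#' `f(x) = 2 lambda beta g G^(beta-1) (1-G)^(-(beta+1))
#'  exp(-w) (1 + exp(-w))^(-2)` with `w = lambda t^beta`. The log density
#' is assembled term by term and never forms the unlogged intermediate.
#'
#' @param x positive numeric vector.
#' @param p an object from [hlow()].
#' @param log return the log density.
#' @return numeric vector of (log) density values.
#' @export
dhlow <- function(x, p, log = FALSE) {
  stopifnot(inherits(p, "hlow"))
  if (any(x <= 0)) stop("x must be strictly positive", call. = FALSE)
  bl <- p$baseline
  w <- .hlow_w(p, x)
  lp <- log(2 * p$lambda) + log(p$beta) + bl$logg(x) +
    (p$beta - 1) * bl$logG(x) - (p$beta + 1) * bl$logS(x) -
    w - 2 * log1p(exp(-w))
  if (any(is.nan(lp)))
    stop("non-finite log-density encountered; check parameters", call. = FALSE)
  if (log) lp else exp(lp)
}

#' Hazard rate function of the Type I HLOW-G family
#'
#' `h(x) = lambda beta g G^(beta-1) (1-G)^(-(beta+1)) / (1 + exp(-w))`,
#' which equals `f(x)/S(x)` identically.
#'
#' @inheritParams dhlow
#' @export
hhlow <- function(x, p, log = FALSE) {
  stopifnot(inherits(p, "hlow"))
  if (any(x <= 0)) stop("x must be strictly positive", call. = FALSE)
  bl <- p$baseline
  w <- .hlow_w(p, x)
  lh <- log(p$lambda) + log(p$beta) + bl$logg(x) +
    (p$beta - 1) * bl$logG(x) - (p$beta + 1) * bl$logS(x) -
    log1p(exp(-w))
  if (log) lh else exp(lh)
}

#' Quantile function of the Type I HLOW-G family
#'
#' Inverts the CDF in closed form down to the baseline:
#' `t = (-log((1-u)/(1+u)) / lambda)^(1/beta)` and
#' `Q(u) = G^{-1}(t/(1+t))`. The inner log is evaluated as
#' `log1p(u) - log1p(-u)` so that `u` near 1 keeps full precision, and the
#' baseline inversion switches to the survival scale when `t > 1`.
#'
#' @param u numeric vector of probabilities in (0, 1).
#' @param p an object from [hlow()].
#' @return numeric vector of quantiles, strictly increasing in `u`.
#' @export
qhlow <- function(u, p) {
  stopifnot(inherits(p, "hlow"))
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)", call. = FALSE)
  z <- (log1p(u) - log1p(-u)) / p$lambda     # -log((1-u)/(1+u)) / lambda
  logt <- log(z) / p$beta
  bl <- p$baseline
  out <- numeric(length(u))
  lower <- logt <= 0
  # t/(1+t) = plogis(log t); 1 - t/(1+t) = plogis(-log t)
  if (any(lower)) out[lower] <- bl$qf(stats::plogis(logt[lower]))
  if (any(!lower)) out[!lower] <- bl$qfs(stats::plogis(-logt[!lower]))
  out
}

#' Random generation from the Type I HLOW-G family
#'
#' Inverse-transform sampling: `n` uniforms are pushed through [qhlow()].
#' A given `seed` fully determines the output; the RNG state of the
#' session is left untouched when `seed` is supplied.
#'
#' @param n number of draws (`n = 0` gives an empty vector).
#' @param p an object from [hlow()].
#' @param seed optional integer seed for reproducible draws.
#' @return numeric vector of `n` positive draws.
#' @export
rhlow <- function(n, p, seed = NULL) {
  stopifnot(inherits(p, "hlow"))
  if (n < 0) stop("n must be nonnegative", call. = FALSE)
  if (n == 0) return(numeric(0))
  u <- with_seed(seed, stats::runif(n))
  qhlow(u, p)
}

# Evaluate `expr` under `seed` (when non-NULL) and restore the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
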