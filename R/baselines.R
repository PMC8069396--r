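# Baseline distributions for the Type I HLOW-G family. Each baseline has
# support (0, Inf) and is carried around as a small list of vectorized
# functions on the log scale, so that the family layer can form the odds
# ratio G/(1-G) without catastrophic cancellation near either tail.

.hlow_baselines <- c("exponential", "rayleigh", "lindley", "weibull",
                     "frechet", "lomax")

# log(1 - exp(-x)) for x > 0, accurate over the whole range
log1mexp <- function(x) {
  ifelse(x < log(2), log(-expm1(-x)), log1p(-exp(-x)))
}

#' Construct a baseline distribution
#'
#' Builds one of the six positive-support baselines used by the Type I
#' HLOW-G family: exponential, Rayleigh, Lindley, Weibull, Frechet or
#' Lomax. The returned object carries the CDF, density, survival and
#' quantile functions (plus log-scale versions used internally) together
#' with the baseline parameter vector `phi`.
#'
#' Parameterizations: exponential `G(x) = 1 - exp(-a x)`; Rayleigh
#' `1 - exp(-a^2 x^2)`; Lindley `1 - (1 + a x / (a + 1)) exp(-a x)`;
#' Weibull `1 - exp(-(x/b)^a)` (`a` shape, `b` scale); Frechet
#' `exp(-(a/x)^b)` (`a` scale, `b` shape); Lomax `1 - (1 + x/b)^(-a)`.
#'
#' @param name baseline name, one of `"exponential"`, `"rayleigh"`,
#'   `"lindley"`, `"weibull"`, `"frechet"`, `"lomax"`.
#' @param phi numeric vector of positive baseline parameters; length 1 for
#'   exponential/Rayleigh/Lindley, length 2 (`a`, `b`) otherwise.
#' @return an object of class `"hlow_baseline"`: a list with elements
#'   `name`, `phi`, `param_names`, and vectorized functions `cdf`, `pdf`,
#'   `sf`, `qf` plus log-scale counterparts `logG`, `logS`, `logg` and the
#'   upper-tail quantile `qfs` (inverse of the survival function).
#' @examples
#' bl <- make_baseline("frechet", c(a = 27.7908, b = 0.2562))
#' bl$cdf(133)
#' @export
make_baseline <- function(name, phi) {
  if (length(name) != 1 || !name %in% .hlow_baselines)
    stop("unsupported baseline '", name, "'; choose one of ",
         paste(.hlow_baselines, collapse = ", "), call. = FALSE)
  phi <- as.numeric(phi)
  arity <- if (name %in% c("exponential", "rayleigh", "lindley")) 1L else 2L
  if (length(phi) != arity)
    stop(sprintf("baseline '%s' takes %d parameter(s), got %d",
                 name, arity, length(phi)), call. = FALSE)
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("baseline parameters must be strictly positive and finite",
         call. = FALSE)

  a <- phi[1]
  b <- if (arity == 2L) phi[2] else NA_real_

  bl <- switch(name,
    exponential = list(
      logG = function(x) log1mexp(a * x),
      logS = function(x) -a * x,
      logg = function(x) log(a) - a * x,
      qf   = function(p) -log1p(-p) / a,
      qfs  = function(q) -log(q) / a,
      param_names = "a"
    ),
    rayleigh = list(
      logG = function(x) log1mexp(a^2 * x^2),
      logS = function(x) -a^2 * x^2,
      logg = function(x) log(2 * a^2 * x) - a^2 * x^2,
      qf   = function(p) sqrt(-log1p(-p)) / a,
      qfs  = function(q) sqrt(-log(q)) / a,
      param_names = "a"
    ),
    lindley = list(
      logS = function(x) log1p(a * x / (a + 1)) - a * x,
      logG = NULL,  # filled below from logS
      logg = function(x) 2 * log(a) - log(a + 1) + log1p(x) - a * x,
      qf   = NULL,  # numeric inversion, filled below
      qfs  = NULL,
      param_names = "a"
    ),
    weibull = list(
      logG = function(x) log1mexp((x / b)^a),
      logS = function(x) -(x / b)^a,
      logg = function(x) log(a / b) + (a - 1) * log(x / b) - (x / b)^a,
      qf   = function(p) b * (-log1p(-p))^(1 / a),
      qfs  = function(q) b * (-log(q))^(1 / a),
      param_names = c("a", "b")
    ),
    frechet = list(
      logG = function(x) -(a / x)^b,
      logS = function(x) log1mexp((a / x)^b),
      logg = function(x) log(b) + b * log(a) - (b + 1) * log(x) - (a / x)^b,
      qf   = function(p) a * (-log(p))^(-1 / b),
      qfs  = function(q) a * (-log1p(-q))^(-1 / b),
      param_names = c("a", "b")
    ),
    lomax = list(
      logG = function(x) log1mexp(a * log1p(x / b)),
      logS = function(x) -a * log1p(x / b),
      logg = function(x) log(a / b) - (a + 1) * log1p(x / b),
      qf   = function(p) b * expm1(-log1p(-p) / a),
      qfs  = function(q) b * expm1(-log(q) / a),
      param_names = c("a", "b")
    )
  )

  if (name == "lindley") {
    logS <- bl$logS
    bl$logG <- function(x) log1mexp(-logS(x))
    # no closed-form inverse; monotone bisection on the log-survival scale
    inv <- function(target_logS) {
      vapply(target_logS, function(ls) {
        if (!is.finite(ls) && ls == -Inf) return(Inf)
        hi <- 1 / a
        while (logS(hi) > ls) hi <- hi * 2
        stats::uniroot(function(x) logS(x) - ls, lower = 0, upper = hi,
                       tol = 1e-13)$root
      }, numeric(1))
    }
    bl$qf <- function(p) inv(log1p(-p))
    bl$qfs <- function(q) inv(log(q))
  }

  bl$name <- name
  bl$phi <- phi
  names(bl$phi) <- bl$param_names
  logG <- bl$logG; logS <- bl$logS; logg <- bl$logg
  bl$cdf <- function(x) ifelse(x <= 0, 0, exp(logG(pmax(x, 0))))
  bl$sf  <- function(x) ifelse(x <= 0, 1, exp(logS(pmax(x, 0))))
  bl$pdf <- function(x) ifelse(x <= 0, 0, exp(logg(pmax(x, .Machine$double.xmin))))
  class(bl) <- "hlow_baseline"
  bl
}

#' @export
print.hlow_baseline <- function(x, ...) {
  cat("Baseline distribution:", x$name, "\n")
  cat("  phi: ", paste(sprintf("%s = %g", x$param_names, x$phi),
                       collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Odds ratio of a baseline CDF
#'
#' Computes `G(x)/(1 - G(x))`, the monotone transform that the odd-Weibull
#' layer of the family exponentiates. Evaluated as
#' `exp(log G - log(1-G))` with both logs computed directly per baseline,
#' which stays accurate when `G` is close to 0 or 1.
#'
#' @param baseline an object from [make_baseline()].
#' @param x positive numeric vector (0 is allowed and returns the limit 0).
#' @return numeric vector of odds values, nondecreasing in `x`.
#' @examples
#' baseline_odds(make_baseline("exponential", 1), 1)  # exp(1) - 1
#' @export
baseline_odds <- function(baseline, x) {
  stopifnot(inherits(baseline, "hlow_baseline"))
  if (any(x < 0)) stop("x must be nonnegative", call. = FALSE)
  ifelse(x == 0, 0, exp(baseline$logG(x) - baseline$logS(x)))
}

# log odds ratio; -Inf at x = 0
baseline_log_odds <- function(baseline, x) {
  ifelse(x == 0, -Inf, baseline$logG(x) - baseline$logS(x))
}
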