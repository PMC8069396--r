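# Goodness-of-fit battery: information criteria, Kolmogorov-Smirnov with
# asymptotic p-value, Anderson-Darling, Cramer-von Mises, and the scaled
# total-time-on-test transform.

#' Information criteria from a maximized log-likelihood
#'
#' `AkIC = 2 negll + 2 df`; `CAkIC = AkIC + 2 df (df+1) / (n - df - 1)`;
#' `BsIC = 2 negll + df log n`; `HQIC = 2 negll + 2 df log(log n)`.
#'
#' @param neg_logL negative maximized log-likelihood.
#' @param df number of fitted parameters.
#' @param n sample size, `n > df + 1`.
#' @return named vector `c(neg_logL, AkIC, CAkIC, BsIC, HQIC)`.
#' @export
information_criteria <- function(neg_logL, df, n) {
  if (n <= df + 1)
    stop("CAkIC undefined: need n > df + 1", call. = FALSE)
  akic <- 2 * neg_logL + 2 * df
  c(neg_logL = neg_logL,
    AkIC = akic,
    CAkIC = akic + 2 * df * (df + 1) / (n - df - 1),
    BsIC = 2 * neg_logL + df * log(n),
    HQIC = 2 * neg_logL + 2 * df * log(log(n)))
}

# upper tail of the Kolmogorov distribution at t = sqrt(n) * D
.kolmogorov_p <- function(t, terms = 100) {
  if (t <= 0) return(1)
  k <- seq_len(terms)
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' `D = max_j max(j/n - z_j, z_j - (j-1)/n)` with `z_j = F(x_(j))`; the
#' p-value comes from the asymptotic Kolmogorov series at `sqrt(n) D`,
#' treating the parameters as known (no estimated-parameter correction).
#'
#' @param p an object from [hlow()].
#' @param x positive numeric sample.
#' @return named vector `c(KS =, p_value =)`.
#' @export
hlow_ks <- function(p, x) {
  if (length(x) < 1) stop("empty sample", call. = FALSE)
  n <- length(x)
  z <- phlow(sort(x), p)
  j <- seq_len(n)
  D <- max(pmax(j / n - z, z - (j - 1) / n))
  c(KS = D, p_value = .kolmogorov_p(sqrt(n) * D))
}

#' Anderson-Darling and Cramer-von Mises statistics
#'
#' Plain `A^2` and `W^2` without small-sample modification:
#' `AD = -n - (1/n) sum (2j-1) (log z_j + log(1 - z_(n+1-j)))` and
#' `CvM = 1/(12n) + sum (z_j - (2j-1)/(2n))^2`. Probabilities at exactly
#' 0 or 1 are clipped to `[1e-12, 1 - 1e-12]` with a warning.
#'
#' @inheritParams hlow_ks
#' @return named vector `c(AD =, CvM =)`.
#' @export
hlow_ad_cvm <- function(p, x) {
  n <- length(x)
  z <- phlow(sort(x), p)
  if (any(z <= 0 | z >= 1)) {
    warning("fitted probabilities at 0 or 1 clipped to [1e-12, 1-1e-12]")
    z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  }
  j <- seq_len(n)
  ad <- -n - mean((2 * j - 1) * (log(z) + log(1 - rev(z))))
  c(AD = ad, CvM = distance_from_z("cvme", z))
}

#' Scaled total-time-on-test transform
#'
#' `T_i = (sum_{j<=i} x_(j) + (n-i) x_(i)) / sum_j x_(j)` plotted against
#' `i/n`; a concave curve diagnoses an increasing failure rate, the
#' diagonal a constant one.
#'
#' @param x positive numeric sample, `n >= 2`.
#' @return data frame with columns `frac` (`i/n`) and `ttt` (`T_i`).
#' @export
ttt_transform <- function(x) {
  if (length(x) < 2) stop("need at least two observations", call. = FALSE)
  if (all(x == 0)) stop("degenerate all-zero sample", call. = FALSE)
  xs <- sort(x)
  n <- length(xs)
  i <- seq_len(n)
  total <- sum(xs)
  data.frame(frac = i / n,
             ttt = (cumsum(xs) + (n - i) * xs) / total)
}

#' Full goodness-of-fit report for a fitted model
#'
#' Bundles the negative log-likelihood, the four information criteria,
#' AD, CvM, KS and its p-value for a Type I HLOW-G model at the given
#' parameter values.
#'
#' @param p an object from [hlow()].
#' @param x positive numeric sample.
#' @param df number of parameters that were fitted (defaults to
#'   `2 + length(phi)`).
#' @return list of class `"hlow_gof"`.
#' @export
hlow_gof <- function(p, x, df = 2 + length(p$baseline$phi)) {
  negll <- hlow_nll(p, x)
  ic <- information_criteria(negll, df, length(x))
  adc <- hlow_ad_cvm(p, x)
  ks <- hlow_ks(p, x)
  structure(c(as.list(ic), as.list(adc), as.list(ks),
              list(df = df, n = length(x))),
            class = "hlow_gof")
}

#' @export
print.hlow_gof <- function(x, ...) {
  cat(sprintf("-logL %.4f  AkIC %.4f  CAkIC %.4f  BsIC %.4f  HQIC %.4f\n",
              x$neg_logL, x$AkIC, x$CAkIC, x$BsIC, x$HQIC))
  cat(sprintf("AD %.4f  CvM %.4f  KS %.4f (p = %.4f)  df %d  n %d\n",
              x$AD, x$CvM, x$KS, x$p_value, x$df, x$n))
  invisible(x)
}
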