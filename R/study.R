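# Monte Carlo comparison of the estimators: replicate generation by
# inverse transform, estimator application, and average-bias / MSE
# summaries over a grid of sample sizes.

#' Average bias and mean squared error
#'
#' Column-wise `AB = mean(est - truth)` and `MSE = mean((est - truth)^2)`
#' over replicate rows.
#'
#' @param estimates matrix of estimates, one replicate per row.
#' @param truth numeric vector of true values, one per column.
#' @return list with `AB` and `MSE` vectors.
#' @export
ab_mse <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  if (ncol(estimates) != length(truth))
    stop("column count does not match the truth vector", call. = FALSE)
  if (nrow(estimates) < 1) stop("need at least one replicate", call. = FALSE)
  dev <- sweep(estimates, 2, truth)
  list(AB = colMeans(dev), MSE = colMeans(dev^2))
}

# deterministic per-replicate seed below 2^31
.study_seed <- function(base_seed, n, j) {
  (base_seed + 7919 * (n %% 1000) + j) %% 2147483587L + 1L
}

#' Monte Carlo estimator-comparison study
#'
#' For each sample size in `n_grid` and each of `reps` replicates, draws
#' a sample from the chosen sub-model at `truth` by inverse transform,
#' applies every requested estimation method, and accumulates the
#' average bias and mean squared error per parameter. Replicates where
#' an estimator fails are dropped from that estimator's summary and
#' counted.
#'
#' @param model `"exponential"` or `"frechet"`.
#' @param truth true parameter vector `(lambda, beta, a[, b])`.
#' @param n_grid increasing vector of sample sizes.
#' @param reps replicates per sample size.
#' @param methods subset of `"mle"`, `"lse"`, `"wlse"`, `"cvme"`,
#'   `"bayes_ip"`, `"bayes_nip"`; entries may also be functions
#'   `f(x, truth)` returning an estimate vector (used for harness
#'   checks).
#' @param loss,kappa Bayes loss settings (see [bayes_estimate()]).
#' @param base_seed integer controlling all replicate seeds.
#' @param starts optimizer starts per classical fit.
#' @param chain_config overrides for the Bayes arm's
#'   [hlow_chain_config()]; the study default shortens the chains to
#'   `draws = 11000, burnin = 1000, thin = 10`.
#' @param ip_variance,nip_variance prior variances for the informative
#'   and non-informative Bayes arms.
#' @return data frame with columns
#'   `model, n, method, parameter, AB, MSE, reps_used`, of class
#'   `"hlow_study"`.
#' @export
hlow_study <- function(model = c("exponential", "frechet"), truth,
                       n_grid = seq(20, 150, by = 5), reps = 1000,
                       methods = c("mle", "lse"), loss = "sel", kappa = NULL,
                       base_seed = 1, starts = 1,
                       chain_config = list(draws = 11000, burnin = 1000,
                                           thin = 10),
                       ip_variance = 0.4, nip_variance = 2.5) {
  model <- match.arg(model)
  stopifnot(reps >= 1, all(diff(n_grid) > 0))
  pn <- .bayes_par_names(model)
  stopifnot(length(truth) == length(pn))
  truth <- stats::setNames(as.numeric(truth), pn)
  p_true <- theta_to_hlow(model, truth)

  one_estimate <- function(method, x, seed) {
    if (is.function(method)) return(method(x, truth))
    if (method %in% c("mle", "lse", "wlse", "cvme")) {
      f <- hlow_fit(x, model, method = method, starts = starts,
                    seed = seed, boot = 0, init = truth)
      return(f$estimates)
    }
    variance <- if (method == "bayes_ip") ip_variance else nip_variance
    prior <- elicit_prior(truth, variance)
    cfg <- do.call(hlow_chain_config,
                   utils::modifyList(list(seed = seed), chain_config))
    chain <- hlow_mcmc(x, model, prior, cfg)
    as.numeric(bayes_estimate(chain, loss = loss, kappa = kappa))
  }

  rows <- list()
  warn <- character(0)
  for (n in n_grid) {
    samples <- lapply(seq_len(reps), function(j)
      rhlow(n, p_true, seed = .study_seed(base_seed, n, j)))
    for (m in seq_along(methods)) {
      method <- methods[[m]]
      mname <- if (is.function(method)) paste0("custom", m) else method
      est <- matrix(NA_real_, reps, length(pn))
      for (j in seq_len(reps)) {
        e <- try(one_estimate(method, samples[[j]],
                              .study_seed(base_seed + 59, n, j)),
                 silent = TRUE)
        if (!inherits(e, "try-error") && all(is.finite(e)))
          est[j, ] <- as.numeric(e)
      }
      ok <- stats::complete.cases(est)
      if (mean(!ok) > 0.2)
        warn <- c(warn, sprintf("%s failed on %.0f%% of replicates at n = %d",
                                mname, 100 * mean(!ok), n))
      if (!any(ok)) next
      s <- ab_mse(est[ok, , drop = FALSE], truth)
      rows[[length(rows) + 1L]] <-
        data.frame(model = model, n = n, method = mname, parameter = pn,
                   AB = s$AB, MSE = s$MSE, reps_used = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "warnings") <- warn
  attr(out, "truth") <- truth
  class(out) <- c("hlow_study", class(out))
  out
}

#' Write study results as tidy CSV
#'
#' @param study result of [hlow_study()].
#' @param path output file path.
#' @export
write_study_csv <- function(study, path) {
  utils::write.csv(as.data.frame(study), path, row.names = FALSE)
  invisible(path)
}
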