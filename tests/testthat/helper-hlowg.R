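# shared helpers: random parameter sets and small seeded samples

# two expectations in the suite are documented known-red comparisons
# against an inconsistent published table; keep the runner from
# terminating the whole suite on their account
options(testthat.progress.max_fails = 200)

baseline_arity <- function(name) {
  if (name %in% c("exponential", "rayleigh", "lindley")) 1L else 2L
}

# a reproducible batch of family parameter sets across all baselines
random_hlow_params <- function(n_sets, seed = 424) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    bl <- sample(c("exponential", "rayleigh", "lindley", "weibull",
                   "frechet", "lomax"), 1)
    hlow(runif(1, 0.5, 2.5), runif(1, 0.5, 2.5), bl,
         phi = runif(baseline_arity(bl), 0.5, 2.5))
  })
}

theta_to_hlow_test <- function(baseline_name, theta) {
  hlow(theta[1], theta[2], baseline_name, phi = theta[-(1:2)])
}

# standard error of a sample mean
se_mean <- function(v) stats::sd(v) / sqrt(length(v))

expect_within_3se <- function(sample_values, theoretical, label = "") {
  se <- se_mean(sample_values)
  expect_lt(abs(mean(sample_values) - theoretical), 3 * se,
            label = paste0(label, " |MC - theory| vs 3 SE"))
}
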