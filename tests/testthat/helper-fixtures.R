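# Shared fixtures: canonical truths and small simulated series built in
# code at test time.

# full-model truth at published-study magnitudes
make_truth <- function(a0 = 1.4, gamma = 2.7, epsilon = 0.3, psi = 0.15,
                       c0 = 30.7, c1 = -2.9e-3,
                       v = c(10, 3.5, 9.8)) {
  full_model_params(vdp_params(a0, gamma, epsilon, psi),
                    trend_params(c0, c1),
                    noise_params(v[1], v[2], v[3]))
}

# quiet truth for tests that need near-noiseless recovery
make_quiet_truth <- function(...) make_truth(..., v = c(0.01, 0.01, 0.01))

# dense multivariate-normal negative log-density: the independent oracle
# for the likelihood (generic matrix algebra, no diagonal shortcuts)
dense_mvn_nll <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  n / 2 * log(2 * pi) + as.numeric(determinant(Sigma)$modulus) / 2 +
    drop(t(r) %*% solve(Sigma) %*% r) / 2
}

# random small uniformly-sampled series with mixed regimes, plus params
random_small_instance <- function(n = 6, seed = 1) {
  set.seed(seed)
  dt <- sample(c(1, 3, 5), 1)
  t <- (seq_len(n) - 1) * dt
  params <- make_truth(a0 = runif(1, 0.3, 3), gamma = runif(1, 0.5, 4),
                       epsilon = runif(1, 0.2, 1),
                       psi = runif(1, -pi, pi),
                       c0 = runif(1, 28, 32), c1 = rnorm(1, 0, 0.01),
                       v = runif(3, 0.5, 12))
  y <- model_mean(t, params) + rnorm(n, 0, 1)
  series <- temperature_series(t, y, start_clock = runif(1, 0, 24))
  list(series = series, params = params)
}
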