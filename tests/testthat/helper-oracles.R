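# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (full enumeration, direct gamma products,
# naive Gibbs) and never call the code paths they check.

# Exact distribution of the number of non-empty cells when n observations
# are allocated over K cells under a symmetric Dirichlet(gamma)-multinomial,
# by enumerating all K^n assignment vectors with their exchangeable
# allocation probabilities  Gamma(K g)/Gamma(K g + n) prod_k Gamma(N_k + g)/Gamma(g).
enumerate_occupancy <- function(K, gamma, n) {
  grids <- rep(list(seq_len(K)), n)
  all_s <- as.matrix(expand.grid(grids))
  probs <- numeric(min(K, n))
  base <- gamma(K * gamma) / gamma(K * gamma + n)
  for (i in seq_len(nrow(all_s))) {
    Nk <- tabulate(all_s[i, ], K)
    p <- base * prod(gamma(Nk + gamma) / gamma(gamma))
    kp <- sum(Nk > 0)
    probs[kp] <- probs[kp] + p
  }
  stats::setNames(probs, seq_along(probs))
}

# Direct (non-log) evaluation of the conditional kernel of K given the
# partition, for small instances where the gamma products stay finite.
direct_kernel_K <- function(Ks, K_plus, Nk, gamma_fn, n, prior) {
  vapply(Ks, function(K) {
    g <- gamma_fn(K)[1]
    factorial(K) / factorial(K - K_plus) *
      gamma(K * g) / gamma(K * g + n) *
      prod(gamma(Nk + g) / gamma(1 + g)) *
      pmf_k(prior, K)
  }, numeric(1))
}

# Conjugate-style Gibbs sampler for a single Gaussian component under the
# independence prior mu ~ N(b0, B0), sigma^-2 ~ G(c0, C0): the K = 1
# reduction of the model, written from scratch.
single_component_gibbs <- function(y, b0, B0, c0, C0, n_iter, burn_in,
                                   thinning = 1) {
  n <- length(y)
  mu <- mean(y)
  prec <- 1 / stats::var(y)
  keep_mu <- keep_s2 <- numeric(0)
  for (it in seq_len(n_iter)) {
    prec <- stats::rgamma(1, c0 + n / 2, rate = C0 + 0.5 * sum((y - mu)^2))
    Bn <- 1 / (1 / B0 + n * prec)
    bn <- Bn * (b0 / B0 + prec * sum(y))
    mu <- stats::rnorm(1, bn, sqrt(Bn))
    if (it > burn_in && (it - burn_in) %% thinning == 0) {
      keep_mu <- c(keep_mu, mu)
      keep_s2 <- c(keep_s2, 1 / prec)
    }
  }
  list(mu = keep_mu, sigma2 = keep_s2)
}

# chi-square goodness-of-fit of integer draws against a pmf, pooling
# low-expectation tail cells so the asymptotics hold
chisq_gof_p <- function(draws, support, probs, min_exp = 5) {
  m <- length(draws)
  obs <- tabulate(factor(draws, levels = support), length(support))
  exp_cnt <- m * probs / sum(probs)
  keep <- exp_cnt >= min_exp
  if (any(!keep)) {
    obs <- c(obs[keep], sum(obs[!keep]))
    exp_cnt <- c(exp_cnt[keep], sum(exp_cnt[!keep]))
  }
  stat <- sum((obs - exp_cnt)^2 / exp_cnt)
  stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
}

# small state constructor for step-level tests
make_state <- function(eta, mu, sigma2, S = integer(0)) {
  mfm_state(K = length(eta), eta = eta, mu = mu, sigma2 = sigma2, S = S)
}

# a resolved config for step-level tests (explicit numeric parameters)
resolved_config <- function(prior = prior_k("uniform", max = 30),
                            weight_mode = "static", weight_param = 1,
                            b0 = 0, B0 = 100, c0 = 2, C0 = 1, K_cap = NULL) {
  cfg <- mfm_config(prior, weight_mode, weight_param, b0 = b0, B0 = B0,
                    c0 = c0, C0 = C0, n_iter = 10, burn_in = 0,
                    K_cap = K_cap)
  mfmclust:::resolve_config(cfg, c(0, 1))  # range only affects unset params
}
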