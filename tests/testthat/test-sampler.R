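# Step-level tests use small hand-built states; chain-level tests use short
# runs on small data sets.

test_that("assignment step handles the degenerate and separated limits", {
  y <- c(-0.3, 0.1, 0.4)
  s1 <- make_state(eta = 1, mu = 0, sigma2 = 1)
  expect_equal(update_assignments(s1, y)$S, c(1L, 1L, 1L))
  # separation limit: log-odds ~ 5000 for y = 0 between means 0 and 100
  set.seed(1)
  s2 <- make_state(eta = c(0.5, 0.5), mu = c(0, 100), sigma2 = c(1, 1))
  S <- update_assignments(s2, rep(0, 50))$S
  expect_true(all(S == 1L))
})

test_that("assignments are symmetric for identical components", {
  set.seed(2)
  s <- make_state(eta = c(0.5, 0.5), mu = c(1, 1), sigma2 = c(2, 2))
  draws <- replicate(200, update_assignments(s, rnorm(20, 1))$S)
  frac1 <- mean(draws == 1L)
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.25 / length(draws)))
})

test_that("assignment frequencies match the categorical posterior", {
  # fixed y, two unequal components: empirical assignment rate matches the
  # normalised eta_k * dnorm weight
  set.seed(3)
  s <- make_state(eta = c(0.7, 0.3), mu = c(0, 1.5), sigma2 = c(1, 0.5))
  y0 <- 0.9
  w <- c(0.7 * dnorm(y0, 0, 1), 0.3 * dnorm(y0, 1.5, sqrt(0.5)))
  p1 <- w[1] / sum(w)
  reps <- 4000
  hits <- replicate(reps, update_assignments(s, y0)$S == 1L)
  expect_lt(abs(mean(hits) - p1), 3 * sqrt(p1 * (1 - p1) / reps))
})

test_that("relabeling compacts non-empty components stably", {
  # the worked 10-observation example: K = 3, third component empty
  S <- c(2L, 1L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L)
  st <- make_state(eta = c(0.2, 0.3, 0.5), mu = c(-1, 0, 1),
                   sigma2 = c(1, 2, 3), S = S)
  out <- count_and_relabel(st)
  expect_equal(out$K_plus, 2L)
  expect_equal(which(out$S == 1L), c(2L, 3L, 5L, 7L, 8L, 9L, 10L))
  expect_equal(which(out$S == 2L), c(1L, 4L, 6L))
  expect_equal(out$counts, c(7L, 3L, 0L))
  # non-empty components keep their parameters (and relative order)
  expect_equal(out$mu, c(-1, 0, 1))

  # gap case: only components 2 and 3 filled -> moved to slots 1 and 2
  st2 <- make_state(eta = c(0.2, 0.3, 0.5), mu = c(-1, 0, 1),
                    sigma2 = c(1, 2, 3), S = c(2L, 3L, 3L))
  out2 <- count_and_relabel(st2)
  expect_equal(out2$K_plus, 2L)
  expect_equal(out2$mu, c(0, 1, -1))
  expect_equal(out2$S, c(1L, 2L, 2L))

  # everything in component 1: identity
  st3 <- make_state(eta = 1, mu = 5, sigma2 = 1, S = rep(1L, 4))
  expect_equal(count_and_relabel(st3)$K_plus, 1L)

  # all components filled: identity relabeling
  st4 <- make_state(eta = c(0.5, 0.5), mu = c(0, 1), sigma2 = c(1, 1),
                    S = c(1L, 2L))
  expect_equal(count_and_relabel(st4)$mu, c(0, 1))
})

test_that("filled-component updates draw from the right conditionals", {
  cfg <- resolved_config(b0 = 0, B0 = 100, c0 = 2, C0 = 1)
  y <- c(rnorm(10, 5, 0.5))
  st <- count_and_relabel(make_state(eta = 1, mu = 5, sigma2 = 1,
                                     S = rep(1L, 10)))
  # precision conditional: shape c0 + N/2 = 7, rate C0 + 0.5 sum (y - mu)^2
  set.seed(11)
  rate <- 1 + 0.5 * sum((y - 5)^2)
  draws <- replicate(4000, 1 / update_filled_components(st, y, cfg)$sigma2[1])
  expect_lt(abs(mean(draws) - 7 / rate), 4 * sqrt(7 / rate^2 / 4000))
  expect_lt(abs(var(draws) - 7 / rate^2), 6 * (7 / rate^2) / sqrt(4000))

  # flat-prior limit for the mean: E[mu | .] -> sample mean of the cluster
  cfg_flat <- resolved_config(b0 = 0, B0 = 1e12, c0 = 2, C0 = 1)
  set.seed(12)
  mus <- replicate(4000, update_filled_components(st, y, cfg_flat)$mu[1])
  expect_lt(abs(mean(mus) - mean(y)), 4 * sd(mus) / sqrt(4000))

  # reaching the update with an empty leading component is a contract bug
  st_bad <- make_state(eta = c(0.5, 0.5), mu = c(0, 1), sigma2 = c(1, 1),
                       S = c(2L, 2L))
  expect_error(update_filled_components(st_bad, c(1, 2), cfg), "non-empty")
})

test_that("single-cluster conjugate recovery of location and scale", {
  set.seed(13)
  y <- rnorm(1000)
  cfg <- resolved_config(b0 = 0, B0 = 1, c0 = 2, C0 = 1)
  st <- count_and_relabel(make_state(eta = 1, mu = 0, sigma2 = 1,
                                     S = rep(1L, length(y))))
  mus <- s2s <- numeric(2000)
  for (i in seq_along(mus)) {
    st <- update_filled_components(st, y, cfg)
    mus[i] <- st$mu[1]; s2s[i] <- st$sigma2[1]
  }
  expect_lt(abs(mean(mus) - 0), 3 * sd(mus))
  expect_lt(abs(mean(s2s) - 1), 3 * sd(s2s))
})

test_that("K given the partition respects its support and kernel", {
  # point-mass prior: K is pinned to its only supported value
  cfg5 <- resolved_config(prior = prior_k("uniform", max = 5))
  st <- count_and_relabel(make_state(eta = c(0.6, 0.4), mu = c(0, 3),
                                     sigma2 = c(1, 1),
                                     S = rep(c(1L, 2L), 5)))
  # under U(1,5) support is 2..5; under U(1,1)-style point mass at 5 use a
  # prior concentrated there via K_cap
  draws <- replicate(100, sample_K_given_partition(st, cfg5, 10))
  expect_true(all(draws >= 2 & draws <= 5))

  # log-space kernel equals the direct gamma-product formula
  for (mode in c("static", "dynamic")) {
    for (wp in c(0.5, 1)) {
      cfg <- resolved_config(prior = prior_k("uniform", max = 15),
                             weight_mode = mode, weight_param = wp)
      lk <- mfmclust:::log_kernel_K(2L, c(7L, 3L), cfg, 10L)
      direct <- direct_kernel_K(lk$K, 2L, c(7, 3), cfg$gamma_fn, 10,
                                cfg$prior)
      expect_equal(lk$logp - lk$logp[1], log(direct) - log(direct[1]),
                   tolerance = 1e-8)
    }
  }

  # empirical draw frequencies match the normalised kernel
  set.seed(14)
  cfg <- resolved_config(prior = prior_k("uniform", max = 30),
                         weight_param = 1)
  lk <- mfmclust:::log_kernel_K(2L, c(7L, 3L), cfg, 10L)
  p <- exp(lk$logp - max(lk$logp)); p <- p / sum(p)
  draws <- replicate(4000, sample_K_given_partition(st2 <- st, cfg, 10))
  expect_gt(chisq_gof_p(draws, lk$K, p), 0.01)
})

test_that("empty components are appended from the prior", {
  cfg <- resolved_config(b0 = 2, B0 = 9, c0 = 2, C0 = 3)
  st <- count_and_relabel(make_state(eta = 1, mu = 0, sigma2 = 1,
                                     S = rep(1L, 5)))
  expect_equal(add_empty_components(st, cfg, 1L)$K, 1L)  # no-op
  out <- add_empty_components(st, cfg, 4L)
  expect_equal(out$K, 4L)
  expect_equal(out$counts, c(5L, 0L, 0L, 0L))
  expect_equal(length(out$mu), 4L)
  # distributional check on the appended parameters
  set.seed(15)
  big <- add_empty_components(st, cfg, 10001L)
  ks_mu <- ks.test(big$mu[-1], "pnorm", 2, 3)
  expect_gt(ks_mu$p.value, 0.01)
  ks_prec <- ks.test(1 / big$sigma2[-1], "pgamma", shape = 2, rate = 3)
  expect_gt(ks_prec$p.value, 0.01)
})

test_that("weights are Dirichlet(gamma + N) draws", {
  cfg <- resolved_config(weight_mode = "static", weight_param = 1)
  st1 <- count_and_relabel(make_state(eta = 1, mu = 0, sigma2 = 1,
                                      S = rep(1L, 3)))
  expect_equal(update_weights(st1, cfg)$eta, 1)

  # K = 2, N = (n, 0): E[eta_2] = gamma / (n + 2 gamma) = 1 / (n + 2)
  set.seed(16)
  n <- 8
  st <- count_and_relabel(make_state(eta = c(0.5, 0.5), mu = c(0, 1),
                                     sigma2 = c(1, 1), S = rep(1L, n)))
  st <- add_empty_components(st, cfg, 2L)
  reps <- 20000
  e2 <- replicate(reps, update_weights(st, cfg)$eta[2])
  m <- 1 / (n + 2)
  v <- m * (1 - m) / (n + 2 + 1)
  expect_lt(abs(mean(e2) - m), 3 * sqrt(v / reps))

  # symmetric prior case: three empty components, gamma = 10
  cfg10 <- resolved_config(weight_mode = "static", weight_param = 10)
  st0 <- make_state(eta = rep(1 / 3, 3), mu = 1:3, sigma2 = rep(1, 3))
  set.seed(17)
  etas <- replicate(5000, update_weights(st0, cfg10)$eta)
  for (k in 1:3) {
    expect_lt(abs(mean(etas[k, ]) - 1 / 3), 3 * sqrt((2 / 9) / 31 / 5000))
  }
})

test_that("full runs are deterministic and respect state invariants", {
  y <- generate_dgp(benchmark_dgps()$gaussian4, seed = 30)$value
  cfg <- mfm_config(prior_k("shifted_bnb"), "dynamic", 1, B0 = 630,
                    C0 = 12.5, n_iter = 1200, burn_in = 200, thinning = 2,
                    seed = 77)
  f1 <- run_mfm(y, cfg)
  f2 <- run_mfm(y, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$counts, f2$counts)
  expect_true(all(f1$trace$K >= f1$trace$K_plus))
  expect_true(all(vapply(f1$counts, sum, numeric(1)) == length(y)))
  expect_true(all(vapply(f1$counts, function(x) all(x > 0), logical(1))))
  expect_error(run_mfm(c(1, NA, 2), cfg), "finite")
  expect_error(mfm_config(prior_k("shifted_bnb"), n_iter = 100,
                          burn_in = 100), "burn_in")
})

test_that("the sweep leaves the prior invariant (successive-conditional run)", {
  # regenerate the data from the current state after every sweep; the chain
  # then targets the joint prior truncated at K_cap, so the sampled K must
  # reproduce the truncated prior-of-K moments
  set.seed(18)
  n <- 5
  cap <- 10L
  pk <- prior_k("truncated_poisson", lambda = 3)
  cfg <- resolved_config(prior = pk, weight_mode = "static",
                         weight_param = 1, b0 = 0, B0 = 4, c0 = 2, C0 = 1,
                         K_cap = cap)
  K0 <- sample_k(pk, 1)
  while (K0 > cap) K0 <- sample_k(pk, 1)
  st <- make_state(eta = rep(1 / K0, K0), mu = rnorm(K0, 0, 2),
                   sigma2 = 1 / rgamma(K0, 2, 1))
  st <- update_weights(st, cfg)
  y <- rnorm(n)
  n_sweep <- 20000
  Ks <- integer(n_sweep)
  for (i in seq_len(n_sweep)) {
    st <- count_and_relabel(update_assignments(st, y))
    st <- update_filled_components(st, y, cfg)
    Knew <- sample_K_given_partition(st, cfg, n)
    st <- add_empty_components(st, cfg, Knew)
    st <- update_weights(st, cfg)
    y <- rnorm(n, st$mu[st$S], sqrt(st$sigma2[st$S]))
    Ks[i] <- st$K
  }
  ks <- seq_len(cap)
  ptrunc <- pmf_k(pk, ks) / sum(pmf_k(pk, ks))
  m_target <- sum(ks * ptrunc)
  # batch-means standard error to account for autocorrelation
  batches <- colMeans(matrix(Ks, nrow = 100))
  se <- sd(batches) / sqrt(length(batches))
  expect_lt(abs(mean(Ks) - m_target), 4 * se)
  emp <- tabulate(Ks, cap) / n_sweep
  expect_lt(tv_distance(setNames(emp, ks), setNames(ptrunc, ks)), 0.05)
})
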