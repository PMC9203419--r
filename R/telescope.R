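#' MFM run configuration
#'
#' Bundles the full prior and MCMC configuration for a telescoping-sampler
#' fit of a univariate Gaussian MFM. The hierarchical model is
#' \deqn{K \sim p(K), \quad \eta | K \sim Dir_K(\gamma_K), \quad
#'       S_i | \eta \sim Mult(\eta),}
#' \deqn{\mu_k \sim N(b_0, B_0), \quad \sigma_k^{-2} \sim G(c_0, C_0), \quad
#'       y_i | S_i = k \sim N(\mu_k, \sigma_k^2),}
#' with the independence prior on \eqn{(\mu_k, \sigma_k^2)}: the component
#' variances do not enter the prior on the means.
#'
#' \code{b0}, \code{B0} and \code{C0} may be left \code{NULL}, in which case
#' they are resolved from the data when the sampler runs: \code{b0} is the
#' midpoint of the data range, \code{B0} the squared range \eqn{R^2} and
#' \code{C0 = 0.02 R^2} (an empirical-Bayes choice that keeps the prior
#' invariant under rescaling of the data).
#'
#' @param prior a \code{\link{prior_k}} object, the prior on K.
#' @param weight_mode \code{"static"} (\eqn{\gamma_K \equiv \gamma}) or
#'   \code{"dynamic"} (\eqn{\gamma_K = \alpha / K}).
#' @param weight_param \eqn{\gamma} or \eqn{\alpha}, positive.
#' @param b0,B0 prior mean and variance of the component means.
#' @param c0,C0 shape and rate of the Gamma prior on the precisions (prior
#'   expectation \eqn{c_0 / C_0}); \eqn{2 c_0} acts as a prior sample size
#'   per component with prior variance \eqn{C_0 / c_0}.
#' @param n_iter total MCMC iterations including burn-in. The default
#'   (210000 with 10000 burn-in and thinning 4) retains 50000 draws.
#' @param burn_in discarded initial iterations.
#' @param thinning keep every \code{thinning}-th post-burn-in draw.
#' @param K_init number of filled components at initialisation.
#' @param K_cap enumeration cap for the draw of K given the partition;
#'   defaults to the prior's \code{1 - 1e-12} truncation point bounded by
#'   100 (the conditional kernel of K carries negligible mass beyond that
#'   for any moderate sample). Recorded in the fit metadata.
#' @param seed optional integer seed; fits are reproducible given it.
#' @return an object of class \code{"mfm_config"}.
#' @export
mfm_config <- function(prior, weight_mode = c("static", "dynamic"),
                       weight_param = 1,
                       b0 = NULL, B0 = NULL, c0 = 2, C0 = NULL,
                       n_iter = 210000, burn_in = 10000, thinning = 4,
                       K_init = 10, K_cap = NULL, seed = NULL) {
  stopifnot(inherits(prior, "prior_k"), weight_param > 0, c0 > 0)
  weight_mode <- match.arg(weight_mode)
  stopifnot_scalar_count(n_iter, "n_iter")
  stopifnot_scalar_count(burn_in, "burn_in", min = 0L)
  stopifnot_scalar_count(thinning, "thinning")
  stopifnot_scalar_count(K_init, "K_init")
  if (burn_in >= n_iter) stop("`burn_in` must be smaller than `n_iter`",
                              call. = FALSE)
  if (!is.null(B0)) stopifnot(B0 > 0)
  if (!is.null(C0)) stopifnot(C0 > 0)
  if (!is.null(K_cap)) stopifnot_scalar_count(K_cap, "K_cap")
  structure(list(prior = prior, weight_mode = weight_mode,
                 weight_param = weight_param,
                 b0 = b0, B0 = B0, c0 = c0, C0 = C0,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 K_init = as.integer(K_init), K_cap = K_cap,
                 seed = seed),
            class = "mfm_config")
}

# Fill data-driven prior parameters and precompute quantities the sampler
# needs every sweep (log prior pmf over 1..K_cap, the gamma_K map).
resolve_config <- function(config, y) {
  stopifnot(inherits(config, "mfm_config"))
  r2 <- diff(range(y))^2
  config$b0 <- config$b0 %||% mean(range(y))
  config$B0 <- config$B0 %||% r2
  config$C0 <- config$C0 %||% (0.02 * r2)
  config$K_cap <- config$K_cap %||% min(support_max_k(config$prior), 100L)
  config$log_pmf_K <- log(pmf_k(config$prior, seq_len(config$K_cap)))
  config$gamma_fn <- gamma_of_K(config$weight_param, config$weight_mode)
  config$resolved <- TRUE
  config
}

#' Sampler state of a Gaussian MFM
#'
#' Plain-list container for the current telescoping-sampler state: the
#' number of components \code{K}, mixture weights \code{eta}, component
#' means \code{mu} and variances \code{sigma2}, assignments \code{S},
#' occupancy counts \code{counts} and the number of filled components
#' \code{K_plus}. After \code{\link{count_and_relabel}} components
#' \code{1..K_plus} are exactly the non-empty ones.
#'
#' @param K number of components.
#' @param eta weight vector on the K-simplex.
#' @param mu,sigma2 component means and variances (length K).
#' @param S integer assignment vector in \code{1..K} (may be empty before
#'   the first assignment update).
#' @return an object of class \code{"mfm_state"}.
#' @export
mfm_state <- function(K, eta, mu, sigma2, S = integer(0)) {
  stopifnot(length(eta) == K, length(mu) == K, length(sigma2) == K,
            all(sigma2 > 0), abs(sum(eta) - 1) < 1e-8)
  counts <- tabulate(S, K)
  structure(list(K = as.integer(K), eta = eta, mu = mu, sigma2 = sigma2,
                 S = as.integer(S), counts = counts,
                 K_plus = sum(counts > 0L)),
            class = "mfm_state")
}

#' Step 1a: sample component assignments
#'
#' Draws each \eqn{S_i} from
#' \eqn{P(S_i = k | \eta, \mu, \sigma^2, y_i) \propto
#'       \eta_k f_N(y_i | \mu_k, \sigma_k^2)},
#' evaluated in log space (Gumbel-max categorical sampling, so no
#' normalisation or underflow in the weights themselves).
#'
#' @param state an \code{mfm_state}.
#' @param y numeric data vector.
#' @return the state with a new assignment vector \code{S} (counts are not
#'   yet refreshed; follow with \code{\link{count_and_relabel}}).
#' @export
update_assignments <- function(state, y) {
  state$S <- .sample_assignments(y, state$eta, state$mu, state$sigma2)
  state
}

#' Step 1b: occupancy counts and stable relabeling
#'
#' Recomputes \eqn{N_k}, sets \eqn{K_+ = \#\{k : N_k > 0\}} and moves the
#' non-empty components (with their parameters and weights) to slots
#' \code{1..K_plus}, preserving their relative order; assignments are
#' re-indexed consistently. All posterior summaries are label-invariant, so
#' any stable compaction is valid.
#'
#' @param state an \code{mfm_state} with assignments set.
#' @export
count_and_relabel <- function(state) {
  counts <- tabulate(state$S, state$K)
  perm <- order(counts == 0L)       # stable: non-empty first, order kept
  pos <- integer(state$K)
  pos[perm] <- seq_len(state$K)
  state$S <- pos[state$S]
  state$eta <- state$eta[perm]
  state$mu <- state$mu[perm]
  state$sigma2 <- state$sigma2[perm]
  state$counts <- counts[perm]
  state$K_plus <- sum(counts > 0L)
  state
}

#' Step 2: update parameters of the filled components
#'
#' For each non-empty component \eqn{k \le K_+}, first draws the precision
#' \eqn{\sigma_k^{-2} \sim G(c_k, C_k)} with \eqn{c_k = c_0 + N_k / 2} and
#' \eqn{C_k = C_0 + \frac12 \sum_{i \in C_k} (y_i - \mu_k)^2}, then the mean
#' \eqn{\mu_k \sim N(b_k, B_k)} with \eqn{B_k = (B_0^{-1} + N_k
#' \sigma_k^{-2})^{-1}} and \eqn{b_k = B_k (B_0^{-1} b_0 + \sigma_k^{-2} N_k
#' \bar y_k)}.
#'
#' @param state an \code{mfm_state} after \code{\link{count_and_relabel}}.
#' @param y numeric data vector.
#' @param config a resolved \code{\link{mfm_config}} (numeric
#'   \code{b0, B0, c0, C0}).
#' @export
update_filled_components <- function(state, y, config) {
  kp <- state$K_plus
  if (kp == 0L || any(state$counts[seq_len(kp)] == 0L)) {
    stop("update_filled_components requires components 1..K_plus non-empty",
         call. = FALSE)
  }
  gs <- rowsum(cbind(y, y * y), state$S)        # rows ordered 1..K_plus
  sum_y <- gs[, 1L]
  sum_y2 <- gs[, 2L]
  Nk <- state$counts[seq_len(kp)]
  mu <- state$mu[seq_len(kp)]
  # precisions first, then means (conditional on the new precisions)
  Ck <- config$C0 + 0.5 * (sum_y2 - 2 * mu * sum_y + Nk * mu^2)
  prec <- stats::rgamma(kp, shape = config$c0 + Nk / 2, rate = Ck)
  Bk <- 1 / (1 / config$B0 + Nk * prec)
  bk <- Bk * (config$b0 / config$B0 + prec * sum_y)
  state$sigma2[seq_len(kp)] <- 1 / prec
  state$mu[seq_len(kp)] <- stats::rnorm(kp, bk, sqrt(Bk))
  state
}

#' Step 3: sample K given the partition
#'
#' Draws a new number of components from
#' \deqn{p(K | C) \propto \frac{K!}{(K - K_+)!}
#'   \frac{\Gamma(K \gamma_K)}{\Gamma(K \gamma_K + n)}
#'   \prod_{k=1}^{K_+} \frac{\Gamma(N_k + \gamma_K)}{\Gamma(1 + \gamma_K)}
#'   \, p(K)}
#' over \eqn{K \in \{K_+, \dots, K_{cap}\}}, evaluated entirely in log-gamma
#' arithmetic. In dynamic mode \eqn{\gamma_K = \alpha / K} varies inside the
#' kernel and the product term. \eqn{n} is the total sample size.
#'
#' @param state an \code{mfm_state} with current counts.
#' @param config a resolved \code{\link{mfm_config}}.
#' @param n sample size.
#' @return the sampled K (integer, always \eqn{\ge K_+}).
#' @export
sample_K_given_partition <- function(state, config, n) {
  lk <- log_kernel_K(state$K_plus, state$counts[seq_len(state$K_plus)],
                     config, n)
  if (all(!is.finite(lk$logp))) {
    stop("Step 3 kernel has zero mass on {K_plus..K_cap}; log-kernel: ",
         paste(sprintf("%.3g", lk$logp), collapse = " "), call. = FALSE)
  }
  lk$K[sample_log_categorical(lk$logp)]
}

# log p(K | C) (unnormalised) on the enumeration grid; exposed internally so
# tests can compare the log-space path against direct evaluation.
log_kernel_K <- function(K_plus, Nk, config, n) {
  Ks <- seq.int(K_plus, max(config$K_cap, K_plus))
  g <- config$gamma_fn(Ks)
  prod_term <- if (config$weight_mode == "static") {
    sum(lgamma(Nk + g[1L]) - lgamma(1 + g[1L]))
  } else {
    colSums(lgamma(outer(Nk, g, "+"))) - K_plus * lgamma(1 + g)
  }
  log_pk <- ifelse(Ks <= length(config$log_pmf_K),
                   config$log_pmf_K[Ks], -Inf)
  logp <- lfactorial(Ks) - lfactorial(Ks - K_plus) +
    lgamma(Ks * g) - lgamma(Ks * g + n) + prod_term + log_pk
  list(K = Ks, logp = logp)
}

#' Step 4: append empty components drawn from the prior
#'
#' Adds \eqn{K - K_+} empty components with \eqn{\mu_k \sim N(b_0, B_0)} and
#' \eqn{\sigma_k^{-2} \sim G(c_0, C_0)}, zero counts and (for now) zero
#' weight; the full weight vector is redrawn in Step 5.
#'
#' @param state an \code{mfm_state} holding only its filled components.
#' @param config a resolved \code{\link{mfm_config}}.
#' @param K_new the value of K sampled in Step 3.
#' @export
add_empty_components <- function(state, config, K_new) {
  kp <- state$K_plus
  stopifnot(K_new >= kp)
  idx <- seq_len(kp)
  n_new <- K_new - kp
  state$mu <- c(state$mu[idx], stats::rnorm(n_new, config$b0, sqrt(config$B0)))
  state$sigma2 <- c(state$sigma2[idx],
                    1 / stats::rgamma(n_new, shape = config$c0, rate = config$C0))
  state$eta <- c(state$eta[idx], numeric(n_new))
  state$counts <- c(state$counts[idx], integer(n_new))
  state$K <- as.integer(K_new)
  state
}

#' Step 5: update the mixture weights
#'
#' Draws \eqn{\eta | N \sim Dir_K(\gamma_1, \dots, \gamma_K)} with
#' \eqn{\gamma_k = \gamma_K + N_k}; in dynamic mode \eqn{\gamma_K = \alpha /
#' K} at the current K.
#'
#' @param state an \code{mfm_state} with counts padded to length K.
#' @param config a resolved \code{\link{mfm_config}}.
#' @export
update_weights <- function(state, config) {
  g <- config$gamma_fn(state$K)[1L]
  w <- stats::rgamma(state$K, shape = g + state$counts, rate = 1)
  state$eta <- w / sum(w)
  state
}

#' Fit a univariate Gaussian MFM with the telescoping sampler
#'
#' Runs the five-step trans-dimensional Gibbs sweep — (1) assignments,
#' relabeling and occupancy; (2) filled-component precisions and means; (3)
#' K given the partition; (4) empty components from the prior; (5) weights —
#' cyclically, starting with Step 1.
#'
#' Initialisation: \code{K_init} filled components with equal weights, all
#' variances set to \eqn{C_0 / 2}, and means at the centroids of a k-means
#' run (10 restarts, seeded from the run seed; \code{K_init} is reduced to
#' the number of distinct data values when necessary).
#'
#' @param y numeric data vector (finite, non-empty).
#' @param config an \code{\link{mfm_config}}.
#' @param keep_params if \code{TRUE}, the retained draws also store the
#'   filled-component means, variances and weights (memory grows with the
#'   trace length).
#' @return an object of class \code{"mfm_fit"}: a list with \code{trace}
#'   (data.frame of \code{iteration}, \code{K}, \code{K_plus}),
#'   \code{counts} (list of sorted filled-component counts per draw),
#'   optional \code{params}, the resolved prior parameters, \code{K_cap},
#'   \code{seed} and \code{runtime}.
#' @examples
#' y <- generate_dgp(benchmark_dgps()$gaussian4, seed = 1)$value
#' cfg <- mfm_config(prior_k("shifted_bnb"), "dynamic", 0.01,
#'                   B0 = 630, C0 = 12.5, n_iter = 3000, burn_in = 500,
#'                   thinning = 2, seed = 7)
#' fit <- run_mfm(y, cfg)
#' summarize_kplus(fit)[c("mode", "entropy")]
#' @export
run_mfm <- function(y, config, keep_params = FALSE) {
  stopifnot(is.numeric(y), length(y) > 0)
  if (any(!is.finite(y))) stop("`y` must be finite", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$seed)) set.seed(config$seed)
  config <- resolve_config(config, y)
  n <- length(y)

  K0 <- min(config$K_init, length(unique(y)))
  centers <- if (K0 > 1L) {
    stats::kmeans(y, centers = K0, nstart = 10)$centers[, 1L]
  } else mean(y)
  state <- mfm_state(K = K0, eta = rep(1 / K0, K0), mu = as.numeric(centers),
                     sigma2 = rep(config$C0 / 2, K0))

  n_keep <- (config$n_iter - config$burn_in) %/% config$thinning
  K_tr <- integer(n_keep)
  Kp_tr <- integer(n_keep)
  it_tr <- integer(n_keep)
  counts_tr <- vector("list", n_keep)
  params_tr <- if (keep_params) vector("list", n_keep)
  kept <- 0L

  for (it in seq_len(config$n_iter)) {
    state <- update_assignments(state, y)
    state <- count_and_relabel(state)
    state <- update_filled_components(state, y, config)
    K_new <- sample_K_given_partition(state, config, n)
    state <- add_empty_components(state, config, K_new)
    state <- update_weights(state, config)
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thinning == 0L) {
      kept <- kept + 1L
      it_tr[kept] <- it
      K_tr[kept] <- state$K
      Kp_tr[kept] <- state$K_plus
      counts_tr[[kept]] <- sort(state$counts[seq_len(state$K_plus)])
      if (keep_params) {
        idx <- seq_len(state$K_plus)
        params_tr[[kept]] <- list(mu = state$mu[idx],
                                  sigma2 = state$sigma2[idx],
                                  eta = state$eta[idx])
      }
    }
  }

  structure(list(
    trace = data.frame(iteration = it_tr[seq_len(kept)],
                       K = K_tr[seq_len(kept)],
                       K_plus = Kp_tr[seq_len(kept)]),
    counts = counts_tr[seq_len(kept)],
    params = if (keep_params) params_tr[seq_len(kept)],
    data = y,
    prior = config$prior,
    weight_mode = config$weight_mode,
    weight_param = config$weight_param,
    b0 = config$b0, B0 = config$B0, c0 = config$c0, C0 = config$C0,
    K_cap = config$K_cap,
    seed = config$seed,
    runtime = proc.time()[["elapsed"]] - t0),
    class = "mfm_fit")
}

#' @export
print.mfm_fit <- function(x, ...) {
  s <- summarize_kplus(x)
  cat(sprintf("<mfm_fit> %s MFM (%s = %g), %d retained draws, n = %d\n",
              x$weight_mode,
              if (x$weight_mode == "static") "gamma" else "alpha",
              x$weight_param, nrow(x$trace), length(x$data)))
  cat(sprintf("  posterior mode of K+: %d (entropy %.3f nats)\n",
              s$mode, s$entropy))
  invisible(x)
}
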