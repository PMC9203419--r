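#' @name kplus_prior
#' @title The prior on the number of data clusters induced by p(K)
#'
#' @description
#' In an MFM model the number of components \eqn{K} and the number of
#' \emph{filled} components \eqn{K_+} (the data clusters) differ: given
#' \eqn{K} and a symmetric Dirichlet prior with parameter \eqn{\gamma_K} on
#' the weights, the \eqn{n} observations are allocated by a
#' Dirichlet-multinomial law over the \eqn{K} cells and \eqn{K_+} is the
#' number of non-empty cells. The prior on \eqn{K_+} is therefore induced
#' jointly by \eqn{p(K)}, \eqn{\gamma_K} and the sample size \eqn{n}.
#'
#' Two computational routes are provided and cross-validated against each
#' other: an exact dynamic-programming recursion over the
#' Dirichlet-multinomial occupancy law, and direct Monte Carlo simulation of
#' weights and allocations.
NULL

new_kplus_dist <- function(probs, n, provenance = c("prior", "posterior"),
                           meta = list()) {
  provenance <- match.arg(provenance)
  stopifnot(all(probs >= 0))
  structure(list(probs = probs, n = n, provenance = provenance, meta = meta),
            class = "kplus_dist")
}

#' @export
print.kplus_dist <- function(x, ...) {
  cat(sprintf("<kplus_dist> %s distribution of K+ (n = %d)\n",
              x$provenance, x$n))
  print(round(x$probs, 4))
  invisible(x)
}

# log weights of the Dirichlet-multinomial composition kernel:
# lw[m] = log Gamma(m + gamma) - log Gamma(gamma) - log m!,  m = 1..n
dirmult_log_w <- function(n, gamma) {
  m <- seq_len(n)
  lgamma(m + gamma) - lgamma(gamma) - lfactorial(m)
}

# log A(n, j) for j = 1..jmax, where
#   A(n, j) = n! * sum over compositions (N_1..N_j >= 1, sum = n)
#             of prod_k Gamma(N_k + gamma) / (Gamma(gamma) N_k!).
# Computed as a j-fold log-space convolution of the composition kernel.
occupancy_log_A <- function(n, jmax, gamma) {
  lw <- dirmult_log_w(n, gamma)
  lc <- rep(-Inf, n)
  lc_prev <- lw
  out <- rep(-Inf, jmax)
  out[1L] <- lfactorial(n) + lw[n]
  if (jmax >= 2L) {
    for (j in 2:jmax) {
      lc <- rep(-Inf, n)
      for (s in j:n) {
        # compositions: last part m = 1..s-j+1, first j-1 parts sum to s-m
        m <- seq_len(s - j + 1L)
        lc[s] <- logsumexp(lc_prev[s - m] + lw[m])
      }
      out[j] <- lfactorial(n) + lc[n]
      lc_prev <- lc
    }
  }
  out
}

#' Distribution of the number of filled components given K
#'
#' Distribution of the number of non-empty cells when \code{n} observations
#' are allocated over \code{K} cells with a symmetric
#' Dirichlet(\code{gamma})-multinomial law.
#'
#' @param K number of cells (mixture components).
#' @param gamma symmetric Dirichlet parameter \eqn{\gamma_K > 0}.
#' @param n number of observations.
#' @param method \code{"exact"} (occupancy recursion) or
#'   \code{"monte_carlo"} (simulated weights and multinomial allocations).
#' @param mc_reps Monte Carlo replications (at least 1000).
#' @return a \code{kplus_dist} with support \code{1:min(K, n)}.
#' @export
conditional_kplus <- function(K, gamma, n, method = c("exact", "monte_carlo"),
                              mc_reps = 10000) {
  stopifnot_scalar_count(K, "K")
  stopifnot_scalar_count(n, "n")
  stopifnot(gamma > 0)
  method <- match.arg(method)
  jmax <- min(K, n)
  if (method == "exact") {
    lp <- occupancy_log_kernel(K, gamma, n, jmax)
    p <- exp(lp - logsumexp(lp))
    probs <- stats::setNames(p, seq_len(jmax))
    new_kplus_dist(probs, n, "prior", meta = list(method = "exact"))
  } else {
    if (mc_reps < 1000) {
      stop("`mc_reps` must be at least 1000 for a meaningful estimate",
           call. = FALSE)
    }
    kp <- simulate_kplus(rep.int(K, mc_reps), gamma_of_K(gamma, "static"), n)
    tab <- tabulate(kp, jmax)
    new_kplus_dist(stats::setNames(tab / mc_reps, seq_len(jmax)), n, "prior",
                   meta = list(method = "monte_carlo", mc_reps = mc_reps))
  }
}

# unnormalised log P(K+ = j | K, gamma, n), j = 1..jmax
occupancy_log_kernel <- function(K, gamma, n, jmax, logA = NULL) {
  j <- seq_len(jmax)
  if (is.null(logA)) logA <- occupancy_log_A(n, jmax, gamma)
  lchoose(K, j) + lgamma(K * gamma) - lgamma(K * gamma + n) + logA[j]
}

gamma_of_K <- function(weight_param, weight_mode) {
  force(weight_param)
  switch(weight_mode,
    static = function(K) rep_len(weight_param, length(K)),
    dynamic = function(K) weight_param / K,
    stop("unknown weight mode"))
}

# one K+ draw per element of Kvec; gamma_fn maps K to gamma_K
simulate_kplus <- function(Kvec, gamma_fn, n) {
  out <- integer(length(Kvec))
  for (i in seq_along(Kvec)) {
    K <- Kvec[i]
    if (K == 1L) { out[i] <- 1L; next }
    g <- gamma_fn(K)[1L]
    w <- stats::rgamma(K, shape = g)
    if (sum(w) <= 0) {
      # gamma so small that all variates underflow: allocation is a point
      # mass on a single uniformly chosen cell
      out[i] <- 1L
      next
    }
    cnt <- stats::rmultinom(1L, n, prob = w)
    out[i] <- sum(cnt > 0L)
  }
  out
}

#' Induced prior on the number of data clusters
#'
#' Marginalises the conditional occupancy law over \eqn{K \sim p(K)}:
#' \deqn{p(K_+ = j) = \sum_K p(K) P(K_+ = j | K, \gamma_K, n),}
#' with \eqn{\gamma_K \equiv \gamma} for the static MFM and
#' \eqn{\gamma_K = \alpha / K} for the dynamic MFM.
#'
#' @param prior a \code{\link{prior_k}} object.
#' @param weight_mode \code{"static"} or \code{"dynamic"}.
#' @param weight_param \eqn{\gamma} (static) or \eqn{\alpha} (dynamic).
#' @param n sample size.
#' @param method \code{"exact"} or \code{"monte_carlo"}.
#' @param mc_reps Monte Carlo replications (at least 1000).
#' @param K_max enumeration cap over K for the exact method; defaults to the
#'   prior's \code{1 - 1e-12} truncation point, bounded by 500. The
#'   enumerated prior mass is renormalised and the cap recorded in the
#'   result metadata.
#' @return a \code{kplus_dist}.
#' @examples
#' pk <- prior_k("uniform", max = 30)
#' ip <- induced_kplus_prior(pk, "static", 10, n = 82)
#' kplus_mode(ip)
#' @export
induced_kplus_prior <- function(prior, weight_mode = c("static", "dynamic"),
                                weight_param, n,
                                method = c("exact", "monte_carlo"),
                                mc_reps = 10000, K_max = NULL) {
  stopifnot(inherits(prior, "prior_k"), weight_param > 0)
  stopifnot_scalar_count(n, "n")
  weight_mode <- match.arg(weight_mode)
  method <- match.arg(method)
  gamma_fn <- gamma_of_K(weight_param, weight_mode)
  K_max <- K_max %||% min(support_max_k(prior), 500L)

  if (method == "exact") {
    Ks <- seq_len(K_max)
    pK <- pmf_k(prior, Ks)
    pK <- pK / sum(pK)
    jmax_all <- min(K_max, n)
    probs <- numeric(jmax_all)
    logA_static <- if (weight_mode == "static") {
      occupancy_log_A(n, jmax_all, weight_param)
    }
    for (K in Ks) {
      if (pK[K] <= 0) next
      jmax <- min(K, n)
      g <- gamma_fn(K)
      logA <- if (weight_mode == "static") logA_static else {
        occupancy_log_A(n, jmax, g)
      }
      lp <- occupancy_log_kernel(K, g, n, jmax, logA = logA)
      p <- exp(lp - logsumexp(lp))
      probs[seq_len(jmax)] <- probs[seq_len(jmax)] + pK[K] * p
    }
    new_kplus_dist(stats::setNames(probs, seq_len(jmax_all)), n, "prior",
                   meta = list(method = "exact", K_max = K_max,
                               weight_mode = weight_mode,
                               weight_param = weight_param))
  } else {
    if (mc_reps < 1000) {
      stop("`mc_reps` must be at least 1000 for a meaningful estimate",
           call. = FALSE)
    }
    Kdraws <- sample_k(prior, mc_reps)
    kp <- simulate_kplus(Kdraws, gamma_fn, n)
    jmax <- max(kp)
    tab <- tabulate(kp, jmax)
    new_kplus_dist(stats::setNames(tab / mc_reps, seq_len(jmax)), n, "prior",
                   meta = list(method = "monte_carlo", mc_reps = mc_reps,
                               weight_mode = weight_mode,
                               weight_param = weight_param))
  }
}

#' Total variation distance between two discrete pmfs
#'
#' @param p,q named probability vectors or \code{kplus_dist} objects; names
#'   are the support points.
#' @export
tv_distance <- function(p, q) {
  p <- as_pmf(p); q <- as_pmf(q)
  supp <- sort(unique(as.integer(c(names(p), names(q)))))
  pv <- p[as.character(supp)]; pv[is.na(pv)] <- 0
  qv <- q[as.character(supp)]; qv[is.na(qv)] <- 0
  sum(abs(pv - qv)) / 2
}

as_pmf <- function(x) {
  if (inherits(x, "kplus_dist")) return(x$probs)
  if (inherits(x, "prior_k")) {
    ks <- seq_len(support_max_k(x))
    return(stats::setNames(pmf_k(x, ks), ks))
  }
  stopifnot(is.numeric(x), !is.null(names(x)))
  x
}

#' Cumulative distribution of a K+ distribution
#' @param x a \code{kplus_dist} or named pmf.
#' @param k integer evaluation points.
#' @export
kplus_cdf <- function(x, k) {
  p <- as_pmf(x)
  supp <- as.integer(names(p))
  vapply(k, function(k0) sum(p[supp <= k0]), numeric(1))
}

#' Mean of a K+ distribution
#' @param x a \code{kplus_dist} or named pmf.
#' @export
kplus_mean <- function(x) {
  p <- as_pmf(x)
  sum(as.integer(names(p)) * p) / sum(p)
}
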