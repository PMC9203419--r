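#' Priors on the number of mixture components K
#'
#' Construct a prior distribution for the number of components \eqn{K \ge 1}
#' of a mixture of finite mixtures (MFM) model. Four families are supported,
#' covering the menu commonly used in Bayesian mixture analysis:
#' \describe{
#'   \item{\code{"uniform"}}{\eqn{K \sim U\{1, \dots, max\}}.}
#'   \item{\code{"truncated_poisson"}}{zero-truncated Poisson,
#'     \eqn{P(K = k) \propto \lambda^k / k!} for \eqn{k \ge 1}. There is no
#'     upper truncation.}
#'   \item{\code{"shifted_geometric"}}{\eqn{K - 1 \sim Geom(p)} with support
#'     starting at 0, so \eqn{P(K = 1) = p}.}
#'   \item{\code{"shifted_bnb"}}{\eqn{K - 1 \sim BNB(r, a, b)}, the
#'     beta-negative-binomial: a negative binomial with size \eqn{r} whose
#'     success probability is Beta(\eqn{a}, \eqn{b}) distributed. The default
#'     parameters (1, 4, 3) give \eqn{E[K] = 2}, \eqn{V[K] = 4}.}
#' }
#'
#' @param family one of \code{"uniform"}, \code{"truncated_poisson"},
#'   \code{"shifted_geometric"}, \code{"shifted_bnb"}.
#' @param max upper bound of the uniform prior (lower bound is 1).
#' @param lambda rate of the truncated Poisson prior.
#' @param prob success probability of the shifted geometric prior.
#' @param r,a,b size and beta shape parameters of the shifted BNB prior.
#'
#' @return an object of class \code{"prior_k"}.
#'
#' @examples
#' prior_moments(prior_k("uniform", max = 30))        # mean 15.5, var 74.92
#' prior_moments(prior_k("truncated_poisson", lambda = 3))
#' tail_prob(prior_k("truncated_poisson", lambda = 3), 10)
#' @export
prior_k <- function(family = c("uniform", "truncated_poisson",
                               "shifted_geometric", "shifted_bnb"),
                    max = 30, lambda = 3, prob = 0.1, r = 1, a = 4, b = 3) {
  family <- match.arg(family)
  params <- switch(family,
    uniform = {
      stopifnot_scalar_count(max, "max")
      list(max = as.integer(max))
    },
    truncated_poisson = {
      stopifnot(length(lambda) == 1L, is.finite(lambda), lambda > 0)
      list(lambda = lambda)
    },
    shifted_geometric = {
      stopifnot(length(prob) == 1L, prob > 0, prob <= 1)
      list(prob = prob)
    },
    shifted_bnb = {
      stopifnot(r > 0, a > 0, b > 0)
      list(r = r, a = a, b = b)
    })
  structure(list(family = family, params = params, support_min = 1L),
            class = "prior_k")
}

#' @export
print.prior_k <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  cat(sprintf("<prior_k> %s(%s)\n", x$family, p))
  m <- prior_moments(x)
  cat(sprintf("  E[K] = %.4g, V[K] = %.4g\n", m[["mean"]], m[["variance"]]))
  invisible(x)
}

#' Prior probability mass function of K
#'
#' @param prior a \code{\link{prior_k}} object.
#' @param k integer vector of evaluation points, all \eqn{\ge 1}.
#' @return \eqn{P(K = k)}, zero outside the support.
#' @export
pmf_k <- function(prior, k) {
  stopifnot(inherits(prior, "prior_k"))
  if (any(!is.finite(k)) || any(k < 1) || any(k != round(k))) {
    stop("`k` must contain integers >= 1", call. = FALSE)
  }
  p <- prior$params
  switch(prior$family,
    uniform = ifelse(k <= p$max, 1 / p$max, 0),
    truncated_poisson =
      stats::dpois(k, p$lambda) / (1 - exp(-p$lambda)),
    shifted_geometric = stats::dgeom(k - 1, p$prob),
    shifted_bnb = dbnb(k - 1, p$r, p$a, p$b))
}

# beta-negative-binomial pmf on x = 0, 1, 2, ...
dbnb <- function(x, r, a, b) {
  out <- numeric(length(x))
  ok <- x >= 0 & x == round(x)
  xo <- x[ok]
  out[ok] <- exp(lgamma(r + xo) - lgamma(xo + 1) - lgamma(r) +
                 lbeta(a + r, b + xo) - lbeta(a, b))
  out
}

#' Truncated support of a prior on K
#'
#' Largest \code{k} needed so that the cumulative prior mass reaches
#' \code{1 - tol}; for bounded families the bound itself. Enumeration-based
#' computations (moment checks, marginalisation over K) use this cap.
#'
#' @param prior a \code{\link{prior_k}} object.
#' @param tol tail mass left beyond the truncation point.
#' @export
support_max_k <- function(prior, tol = 1e-12) {
  stopifnot(inherits(prior, "prior_k"))
  if (prior$family == "uniform") return(prior$params$max)
  hi <- 64L
  repeat {
    cum <- sum(pmf_k(prior, seq_len(hi)))
    if (cum >= 1 - tol || hi > 2^22) break
    hi <- hi * 2L
  }
  cum <- cumsum(pmf_k(prior, seq_len(hi)))
  which(cum >= 1 - tol)[1L] %||% hi
}

#' Prior mean and variance of K
#'
#' Closed-form moments where available (uniform, truncated Poisson, shifted
#' geometric, shifted BNB with \code{a > 2}); otherwise truncated summation
#' over the support holding \code{1 - 1e-12} of the mass.
#'
#' @param prior a \code{\link{prior_k}} object.
#' @return named numeric vector \code{c(mean = , variance = )}.
#' @export
prior_moments <- function(prior) {
  stopifnot(inherits(prior, "prior_k"))
  p <- prior$params
  out <- switch(prior$family,
    uniform = {
      u <- p$max
      c(mean = (1 + u) / 2, variance = (u^2 - 1) / 12)
    },
    truncated_poisson = {
      z <- 1 - exp(-p$lambda)
      m <- p$lambda / z
      ex2 <- (p$lambda^2 + p$lambda) / z
      c(mean = m, variance = ex2 - m^2)
    },
    shifted_geometric = {
      q <- 1 - p$prob
      c(mean = 1 / p$prob, variance = q / p$prob^2)
    },
    shifted_bnb = {
      if (p$a > 2) {
        m0 <- p$r * p$b / (p$a - 1)
        v0 <- p$r * (p$r + p$a - 1) * p$b * (p$b + p$a - 1) /
          ((p$a - 2) * (p$a - 1)^2)
        c(mean = 1 + m0, variance = v0)
      } else {
        ks <- seq_len(support_max_k(prior))
        pk <- pmf_k(prior, ks)
        m <- sum(ks * pk) / sum(pk)
        c(mean = m, variance = sum(ks^2 * pk) / sum(pk) - m^2)
      }
    })
  out
}

#' Prior tail probability P(K > k0)
#'
#' @param prior a \code{\link{prior_k}} object.
#' @param k0 integer threshold, \eqn{\ge 1}.
#' @export
tail_prob <- function(prior, k0) {
  stopifnot_scalar_count(k0, "k0")
  p <- prior$params
  switch(prior$family,
    uniform = max(0, (p$max - k0) / p$max),
    # k0 >= 1, so truncating zero only rescales the Poisson tail
    truncated_poisson =
      stats::ppois(k0, p$lambda, lower.tail = FALSE) / (1 - exp(-p$lambda)),
    shifted_geometric = stats::pgeom(k0 - 1, p$prob, lower.tail = FALSE),
    shifted_bnb = 1 - sum(dbnb(0:(k0 - 1), p$r, p$a, p$b)))
}

#' Draw from a prior on K
#'
#' Inverse-CDF sampling over the truncated support (tail mass below
#' \code{1e-12} is folded into the last atom).
#'
#' @param prior a \code{\link{prior_k}} object.
#' @param m number of draws.
#' @return integer vector of length \code{m}.
#' @export
sample_k <- function(prior, m) {
  stopifnot_scalar_count(m, "m")
  ks <- seq_len(support_max_k(prior))
  pk <- pmf_k(prior, ks)
  sample(ks, m, replace = TRUE, prob = pk)
}
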