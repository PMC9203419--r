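#' Maximum-likelihood EM for univariate Gaussian mixtures
#'
#' Fits a K-component Gaussian mixture by EM, with either unequal
#' component variances or a single variance shared by all components
#' (tied in the M-step). A variance floor of \code{1e-6 * var(y)} guards
#' against the likelihood blowing up on singleton components; a fit that
#' repeatedly hits the floor is flagged as degenerate, not rejected.
#'
#' @param y numeric data vector.
#' @param K number of components, \eqn{1 \le K < n}.
#' @param variance_model \code{"unequal"} or \code{"equal"}.
#' @param init \code{"hclust"} (Ward clustering of the data into K groups)
#'   or \code{"random"} (means drawn from the data, pooled variance).
#' @param init_groups optional integer vector in \code{1..K} assigning each
#'   observation to an initial group; overrides \code{init}. Used by
#'   \code{\link{select_K_bic}} to reuse one clustering tree across K.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return an object of class \code{"em_fit"}: weights, means, variances,
#'   \code{loglik}, \code{bic}, \code{converged}, \code{degenerate},
#'   \code{n_iter_used} and the log-likelihood trace. The BIC is
#'   \eqn{-2 \ell + p \log n} with \eqn{p = (K - 1) + K + K} free parameters
#'   for the unequal model and \eqn{(K - 1) + K + 1} for the equal one.
#' @export
em_fit <- function(y, K, variance_model = c("unequal", "equal"),
                   init = c("hclust", "random"), tol = 1e-8,
                   max_iter = 1000, init_groups = NULL) {
  variance_model <- match.arg(variance_model)
  init <- match.arg(init)
  n <- length(y)
  stopifnot_scalar_count(K, "K")
  if (n <= K) stop("need more observations than components", call. = FALSE)
  floor_var <- 1e-6 * stats::var(y)

  if (K == 1L) {
    v <- max(mean((y - mean(y))^2), floor_var)   # MLE variance
    ll <- sum(stats::dnorm(y, mean(y), sqrt(v), log = TRUE))
    return(new_em_fit(1L, variance_model, 1, mean(y), v, ll, n,
                      converged = TRUE, degenerate = FALSE,
                      n_iter_used = 0L, ll_trace = ll))
  }

  if (!is.null(init_groups) || init == "hclust") {
    grp <- init_groups %||%
      stats::cutree(stats::hclust(stats::dist(y), method = "ward.D2"), K)
    stopifnot(length(grp) == n, all(grp >= 1), all(grp <= K))
    w <- as.numeric(tabulate(grp, K)) / n
    mu <- vapply(seq_len(K), function(k) mean(y[grp == k]), numeric(1))
    v0 <- vapply(seq_len(K), function(k) {
      yk <- y[grp == k]
      if (length(yk) > 1) stats::var(yk) else stats::var(y) / K
    }, numeric(1))
  } else {
    w <- rep(1 / K, K)
    mu <- sample(y, K)
    v0 <- rep(stats::var(y), K)
  }
  v <- pmax(if (variance_model == "equal") rep(mean(v0), K) else v0,
            floor_var)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  floored <- FALSE
  iter <- 0L
  ydesign <- cbind(y * y, y, 1)
  repeat {
    iter <- iter + 1L
    # E-step in log space; the component log-density is quadratic in y, so
    # the n x K matrix is a single matrix product
    coef <- rbind(-0.5 / v, mu / v,
                  log(w) - 0.5 * mu^2 / v - 0.5 * log(2 * pi * v))
    lp <- ydesign %*% coef
    m <- lp[cbind(seq_len(n), max.col(lp, ties.method = "first"))]
    # clamp at exp(-45) ~ 3e-20: below the precision of the normalising
    # sum, and avoids slow subnormal exp calls for far-away components
    r <- exp(pmax(lp - m, -45))
    rs <- rowSums(r)
    ll <- sum(m + log(rs))
    r <- r / rs
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    # M-step
    nk <- colSums(r)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(r * y) / nk
    dev2 <- (matrix(y, n, K) - rep(mu, each = n))^2
    ss <- colSums(r * dev2)
    if (variance_model == "equal") {
      v <- rep(sum(ss) / n, K)
    } else {
      v <- ss / nk
    }
    if (any(v < floor_var)) floored <- TRUE
    v <- pmax(v, floor_var)
  }
  new_em_fit(K, variance_model, w, mu, v, ll, n, converged,
             degenerate = floored, n_iter_used = iter, ll_trace = ll_trace)
}

new_em_fit <- function(K, variance_model, w, mu, v, ll, n, converged,
                       degenerate, n_iter_used, ll_trace) {
  p <- (K - 1) + K + if (variance_model == "equal") 1 else K
  structure(list(K = as.integer(K), variance_model = variance_model,
                 weights = as.numeric(w), means = as.numeric(mu),
                 variances = as.numeric(v), loglik = ll,
                 bic = -2 * ll + p * log(n), n_params = p,
                 converged = converged, degenerate = degenerate,
                 n_iter_used = n_iter_used, loglik_trace = ll_trace),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("<em_fit> K = %d (%s variances), loglik = %.3f, BIC = %.3f%s\n",
              x$K, x$variance_model, x$loglik, x$bic,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' BIC model selection over the number of components
#'
#' Fits Gaussian mixtures by EM for each K in \code{K_range} (hierarchical
#' clustering initialisation plus \code{restarts} random restarts per K and
#' variance model, keeping the best log-likelihood) and returns the fit
#' minimising the BIC. \code{approach = "best_of_both"} searches across both
#' the equal- and unequal-variance families.
#'
#' @param y numeric data vector.
#' @param K_range integer candidate values of K.
#' @param approach \code{"unequal"}, \code{"equal"} or
#'   \code{"best_of_both"}.
#' @param restarts random restarts per (K, model) in addition to the
#'   hierarchical-clustering start.
#' @param tol,max_iter passed to \code{\link{em_fit}}.
#' @return the BIC-minimising \code{em_fit}.
#' @export
select_K_bic <- function(y, K_range = 1:15,
                         approach = c("unequal", "equal", "best_of_both"),
                         restarts = 5, tol = 1e-8, max_iter = 1000) {
  approach <- match.arg(approach)
  stopifnot(length(K_range) >= 1)
  models <- if (approach == "best_of_both") c("equal", "unequal") else approach
  hc <- if (any(K_range > 1)) {
    stats::hclust(stats::dist(y), method = "ward.D2")
  }
  best <- NULL
  for (model in models) {
    for (K in K_range) {
      if (K >= length(y)) next
      grp <- if (K > 1L) stats::cutree(hc, K)
      fit <- em_fit(y, K, model, tol = tol, max_iter = max_iter,
                    init_groups = grp)
      if (K > 1L) {
        for (r in seq_len(restarts)) {
          cand <- em_fit(y, K, model, init = "random", tol = tol,
                         max_iter = max_iter)
          if (cand$loglik > fit$loglik) fit <- cand
        }
      }
      if (is.null(best) || fit$bic < best$bic) best <- fit
    }
  }
  best
}
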