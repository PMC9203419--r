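#' Posterior distribution of the number of data clusters
#'
#' Relative frequencies of \eqn{K_+} over the retained MCMC draws.
#'
#' @param x an \code{mfm_fit} object (see \code{\link{run_mfm}}) or an
#'   integer vector of retained \eqn{K_+} draws.
#' @return a \code{kplus_dist} with provenance \code{"posterior"}.
#' @export
kplus_posterior <- function(x) {
  kp <- if (inherits(x, "mfm_fit")) x$trace$K_plus else x
  if (length(kp) == 0) stop("empty trace", call. = FALSE)
  stopifnot(all(kp >= 1), all(kp == round(kp)))
  tab <- tabulate(kp, max(kp))
  n <- if (inherits(x, "mfm_fit")) length(x$data) else NA_integer_
  new_kplus_dist(stats::setNames(tab / length(kp), seq_along(tab)),
                 n = n %||% NA_integer_, provenance = "posterior",
                 meta = list(draws = length(kp)))
}

#' Posterior mode of the number of data clusters
#'
#' The point estimator of the number of data clusters: the argmax of the
#' \eqn{K_+} distribution. Ties are broken towards the \emph{smallest}
#' \eqn{K_+}, favouring the sparser solution; a tie is reported via a
#' message.
#'
#' @param x a \code{kplus_dist} or named pmf.
#' @export
kplus_mode <- function(x) {
  p <- as_pmf(x)
  supp <- as.integer(names(p))
  mx <- max(p)
  at <- supp[p >= mx - 1e-15]
  if (length(at) > 1L) {
    message("kplus_mode: tie among {", paste(at, collapse = ", "),
            "}; reporting the smallest")
  }
  min(at)
}

#' Shannon entropy of a discrete distribution (in nats)
#'
#' \eqn{-\sum_i p_i \log p_i} with the convention \eqn{0 \log 0 = 0};
#' computed over the observed support only. A point mass has entropy 0; the
#' uniform distribution over \eqn{m} values has entropy \eqn{\log m}.
#'
#' @param x a \code{kplus_dist} or a (named or unnamed) probability vector.
#' @export
entropy <- function(x) {
  p <- if (inherits(x, "kplus_dist")) x$probs else x
  stopifnot(is.numeric(p), all(p >= 0))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) + 0  # adding 0 turns a signed -0 into a plain 0
}

#' Summarise a posterior of K+ by its pmf, mode and entropy
#'
#' @param x an \code{mfm_fit} or integer vector of \eqn{K_+} draws.
#' @return a list with elements \code{pmf} (a \code{kplus_dist}),
#'   \code{mode} and \code{entropy}.
#' @export
summarize_kplus <- function(x) {
  pmf <- kplus_posterior(x)
  list(pmf = pmf, mode = kplus_mode(pmf), entropy = entropy(pmf))
}
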