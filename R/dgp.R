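#' Synthetic mixture data with fixed cluster sizes
#'
#' Specify a univariate mixture data-generating process whose cluster sizes
#' are \emph{fixed} (deterministic allocation), not multinomial: component
#' \eqn{k} contributes exactly \code{sizes[k] * scale} observations.
#'
#' @param family \code{"gaussian"} (components parameterised by mean and sd)
#'   or \code{"uniform"} (lower and upper bound).
#' @param params two-column numeric matrix, one row per component:
#'   \code{cbind(mean, sd)} or \code{cbind(lower, upper)}.
#' @param sizes positive integer base cluster sizes, one per component.
#' @param scale positive integer multiplier applied to all sizes.
#' @param multinomial if \code{TRUE}, sizes are instead drawn from a
#'   multinomial with probabilities proportional to \code{sizes}; off by
#'   default.
#' @return an object of class \code{"dgp_spec"}.
#' @export
dgp_spec <- function(family = c("gaussian", "uniform"), params, sizes,
                     scale = 1L, multinomial = FALSE) {
  family <- match.arg(family)
  params <- as.matrix(params)
  stopifnot(ncol(params) == 2L, nrow(params) == length(sizes),
            all(sizes >= 1), all(sizes == round(sizes)))
  stopifnot_scalar_count(scale, "scale")
  if (family == "uniform" && any(params[, 1] >= params[, 2])) {
    stop("uniform components need lower < upper", call. = FALSE)
  }
  if (family == "gaussian" && any(params[, 2] <= 0)) {
    stop("gaussian components need sd > 0", call. = FALSE)
  }
  structure(list(family = family, params = params,
                 sizes = as.integer(sizes), scale = as.integer(scale),
                 multinomial = isTRUE(multinomial)),
            class = "dgp_spec")
}

#' @export
print.dgp_spec <- function(x, ...) {
  cat(sprintf("<dgp_spec> %s mixture, %d components, n = %d\n",
              x$family, nrow(x$params), sum(x$sizes) * x$scale))
  invisible(x)
}

#' Benchmark data-generating processes
#'
#' The two 4-component benchmark processes used throughout the package's
#' simulation experiments, both with base cluster sizes (5, 55, 30, 10):
#' \describe{
#'   \item{\code{"gaussian4"}}{means (9.5, 20, 24.5, 33), standard
#'     deviations (0.25, 1, 1, 0.5).}
#'   \item{\code{"uniform4"}}{uniform components with bounds
#'     (9,10), (18,22), (22,27), (32,34) — a misspecified target for a
#'     Gaussian mixture fit.}
#' }
#'
#' @param scale integer size multiplier (scale 1 gives n = 100, scale 10
#'   gives n = 1000).
#' @return named list of two \code{dgp_spec} objects.
#' @export
benchmark_dgps <- function(scale = 1L) {
  sizes <- c(5L, 55L, 30L, 10L)
  list(
    gaussian4 = dgp_spec("gaussian",
                         cbind(mean = c(9.5, 20, 24.5, 33),
                               sd = c(0.25, 1, 1, 0.5)),
                         sizes, scale),
    uniform4 = dgp_spec("uniform",
                        cbind(lower = c(9, 18, 22, 32),
                              upper = c(10, 22, 27, 34)),
                        sizes, scale))
}

#' Generate data from a mixture DGP
#'
#' Draws exactly \code{sizes[k] * scale} observations from each component,
#' then shuffles rows (labels stay aligned with values) so downstream code
#' cannot exploit the generation order.
#'
#' @param dgp a \code{\link{dgp_spec}}.
#' @param seed optional integer seed; the draw is deterministic given it.
#' @return \code{data.frame} with columns \code{value} and \code{label}
#'   (component index).
#' @export
generate_dgp <- function(dgp, seed = NULL) {
  stopifnot(inherits(dgp, "dgp_spec"))
  if (!is.null(seed)) set.seed(seed)
  sizes <- dgp$sizes * dgp$scale
  if (dgp$multinomial) {
    n <- sum(sizes)
    sizes <- as.vector(stats::rmultinom(1L, n, prob = dgp$sizes))
  }
  vals <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    vals[[k]] <- if (dgp$family == "gaussian") {
      stats::rnorm(sizes[k], dgp$params[k, 1], dgp$params[k, 2])
    } else {
      stats::runif(sizes[k], dgp$params[k, 1], dgp$params[k, 2])
    }
  }
  out <- data.frame(value = unlist(vals),
                    label = rep.int(seq_along(sizes), sizes))
  out[sample.int(nrow(out)), , drop = FALSE]
}
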