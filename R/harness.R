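#' Factorial design space for prior-sensitivity experiments
#'
#' A full-factorial grid over the prior on K, the Dirichlet mode and
#' parameter, and the component-prior parameters \code{B0} and \code{C0}
#' (with \code{b0} fixed at the data midpoint and \code{c0} fixed, by
#' default at 2).
#'
#' @param priors named list of \code{\link{prior_k}} objects.
#' @param weight_modes subset of \code{c("static", "dynamic")}.
#' @param weight_params numeric values of \eqn{\gamma} / \eqn{\alpha}.
#' @param B0,C0 numeric grids for the component-prior parameters.
#' @param c0 fixed shape of the precision prior.
#' @return an object of class \code{"mfm_design"}.
#' @export
design_space <- function(priors, weight_modes = c("static", "dynamic"),
                         weight_params = c(0.01, 1, 10),
                         B0 = c(6.3, 20, 100, 630),
                         C0 = c(0.5, 1, 5, 12.5), c0 = 2) {
  stopifnot(is.list(priors), length(priors) >= 1,
            !is.null(names(priors)), all(nzchar(names(priors))),
            all(vapply(priors, inherits, logical(1), "prior_k")),
            all(weight_modes %in% c("static", "dynamic")))
  structure(list(priors = priors, weight_modes = weight_modes,
                 weight_params = weight_params, B0 = B0, C0 = C0, c0 = c0),
            class = "mfm_design")
}

#' @export
print.mfm_design <- function(x, ...) {
  cat(sprintf("<mfm_design> %d cells (%d priors x %d modes x %d params x %d B0 x %d C0)\n",
              nrow(design_cells(x)), length(x$priors), length(x$weight_modes),
              length(x$weight_params), length(x$B0), length(x$C0)))
  invisible(x)
}

#' The default sensitivity designs
#'
#' \code{benchmark_design()} is the 384-cell grid used for an 82-observation
#' velocity-style data set: the four standard priors on K (truncated
#' Poisson(3), shifted BNB(1,4,3), shifted geometric(0.1), uniform on
#' 1..30), static and dynamic MFM, \eqn{\gamma, \alpha \in \{0.01, 1, 10\}},
#' \eqn{B_0 \in \{6.3, 20, 100, 630\}} and \eqn{C_0 \in \{0.5, 1, 5,
#' 12.5\}}. \code{simulation_design()} restricts \code{B0} and \code{C0} to
#' their extreme values and widens the uniform prior to 1..100 (96 cells),
#' the grid used for the larger synthetic-data studies.
#'
#' @return an \code{\link{design_space}} object.
#' @export
benchmark_design <- function() {
  design_space(priors = list(
    "trPois(3)" = prior_k("truncated_poisson", lambda = 3),
    "BNB(1,4,3)" = prior_k("shifted_bnb", r = 1, a = 4, b = 3),
    "Geom(0.1)" = prior_k("shifted_geometric", prob = 0.1),
    "U(1,30)" = prior_k("uniform", max = 30)))
}

#' @rdname benchmark_design
#' @export
simulation_design <- function() {
  design_space(priors = list(
    "trPois(3)" = prior_k("truncated_poisson", lambda = 3),
    "BNB(1,4,3)" = prior_k("shifted_bnb", r = 1, a = 4, b = 3),
    "Geom(0.1)" = prior_k("shifted_geometric", prob = 0.1),
    "U(1,100)" = prior_k("uniform", max = 100)),
    B0 = c(6.3, 630), C0 = c(0.5, 12.5))
}

#' Enumerate the cells of a design
#'
#' @param design an \code{\link{design_space}} object.
#' @return data.frame with one row per cell: \code{cell}, \code{prior},
#'   \code{weight_mode}, \code{weight_param}, \code{B0}, \code{C0}.
#' @export
design_cells <- function(design) {
  stopifnot(inherits(design, "mfm_design"))
  g <- expand.grid(prior = names(design$priors),
                   weight_mode = design$weight_modes,
                   weight_param = design$weight_params,
                   B0 = design$B0, C0 = design$C0,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cbind(cell = seq_len(nrow(g)), g)
}

#' Run a factorial prior-sensitivity experiment
#'
#' Fits the MFM once per design cell (and per replicate data set) and
#' records the posterior mode and entropy of \eqn{K_+} for each cell.
#' Per-cell seeds are derived deterministically from \code{master_seed}, so
#' a rerun with the same seed reproduces every cell. When \code{out_dir} is
#' given, each completed cell is persisted as a small CSV and skipped on
#' restart, making long runs resumable. A failing cell is recorded with its
#' error message and the run continues.
#'
#' @param data numeric data vector, or \code{NULL} to simulate from
#'   \code{dgp}.
#' @param design an \code{\link{design_space}}.
#' @param dgp a \code{\link{dgp_spec}} used when \code{data} is
#'   \code{NULL}; one data set is generated per replicate.
#' @param replicates number of replicate data sets (1 for fixed data).
#' @param mcmc list of MCMC overrides passed to \code{\link{mfm_config}}
#'   (\code{n_iter}, \code{burn_in}, \code{thinning}, \code{K_init}). The
#'   \code{fast_mcmc()} profile (20000 + 2000 burn-in, thinning 4) is a
#'   documented reduced profile for desk-scale runs; full-length settings
#'   are the \code{mfm_config} defaults.
#' @param master_seed integer master seed.
#' @param out_dir optional directory for per-cell result files.
#' @param fit_fn function \code{(y, config) -> mfm_fit}; defaults to
#'   \code{\link{run_mfm}}. Tests substitute a stub here to exercise the
#'   bookkeeping without MCMC cost.
#' @return data.frame of cell results: design factors plus \code{replicate},
#'   \code{mode}, \code{entropy}, \code{seed}, \code{ok}, \code{message}.
#' @export
run_design <- function(data = NULL, design, dgp = NULL, replicates = 1,
                       mcmc = fast_mcmc(), master_seed = 1,
                       out_dir = NULL, fit_fn = run_mfm) {
  stopifnot(inherits(design, "mfm_design"))
  if (is.null(data) && is.null(dgp)) stop("supply `data` or `dgp`",
                                          call. = FALSE)
  cells <- design_cells(design)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- vector("list", nrow(cells) * replicates)
  i <- 0L
  for (rep_id in seq_len(replicates)) {
    y <- if (!is.null(data)) data else {
      generate_dgp(dgp, seed = derive_seed(master_seed, c(0L, rep_id)))$value
    }
    for (ci in seq_len(nrow(cells))) {
      i <- i + 1L
      cl <- cells[ci, ]
      seed <- derive_seed(master_seed, c(rep_id, ci))
      path <- if (!is.null(out_dir)) {
        file.path(out_dir, sprintf("cell_%04d_rep_%03d.csv", ci, rep_id))
      }
      if (!is.null(path) && file.exists(path)) {
        rows[[i]] <- utils::read.csv(path, stringsAsFactors = FALSE)
        next
      }
      res <- tryCatch({
        cfg <- mfm_config(prior = design$priors[[cl$prior]],
                          weight_mode = cl$weight_mode,
                          weight_param = cl$weight_param,
                          B0 = cl$B0, c0 = design$c0, C0 = cl$C0,
                          n_iter = mcmc$n_iter %||% 22000,
                          burn_in = mcmc$burn_in %||% 2000,
                          thinning = mcmc$thinning %||% 4,
                          K_init = mcmc$K_init %||% 10,
                          seed = seed)
        fit <- fit_fn(y, cfg)
        s <- summarize_kplus(fit)
        data.frame(cl, replicate = rep_id, mode = s$mode,
                   entropy = s$entropy, seed = seed, ok = TRUE,
                   message = "", stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(cl, replicate = rep_id, mode = NA_integer_,
                   entropy = NA_real_, seed = seed, ok = FALSE,
                   message = conditionMessage(e), stringsAsFactors = FALSE)
      })
      if (!is.null(path)) utils::write.csv(res, path, row.names = FALSE)
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reduced MCMC profile for desk-scale sensitivity runs
#' @export
fast_mcmc <- function() {
  list(n_iter = 22000, burn_in = 2000, thinning = 4, K_init = 10)
}

#' Marginal means of the estimated number of data clusters
#'
#' For each level of one design factor, averages the per-cell posterior
#' modes of \eqn{K_+} across all other factors (and replicates). This is
#' the marginal-effect summary of a full-factorial sensitivity analysis.
#'
#' @param results data.frame from \code{\link{run_design}}.
#' @param factor one of \code{"weight_mode"}, \code{"weight_param"},
#'   \code{"prior"}, \code{"B0"}, \code{"C0"}.
#' @return data.frame with columns \code{level}, \code{mean_mode},
#'   \code{n_cells}.
#' @export
marginal_table <- function(results, factor = c("weight_mode", "weight_param",
                                               "prior", "B0", "C0")) {
  factor <- match.arg(factor)
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  res <- results[results$ok & !is.na(results$mode), , drop = FALSE]
  counts <- table(res[[factor]])
  if (length(unique(counts)) > 1) {
    warning("results do not cover a balanced factorial in `", factor, "`")
  }
  levels <- unique(res[[factor]])
  out <- data.frame(
    level = levels,
    mean_mode = vapply(levels, function(l) {
      mean(res$mode[res[[factor]] == l])
    }, numeric(1)),
    n_cells = vapply(levels, function(l) {
      sum(res[[factor]] == l)
    }, numeric(1)))
  rownames(out) <- NULL
  out
}

#' Mode/entropy panels of a sensitivity run
#'
#' Produces the per-(weight mode, weight parameter) panel table of posterior
#' mode and entropy against the prior on K, with priors ordered by their
#' prior mean of \eqn{K^2} (squared mean plus variance), coloured by
#' \code{B0} and shaped by \code{C0}. Returns the tidy table and, when
#' \pkg{ggplot2} is installed, the two panel plots.
#'
#' @param results data.frame from \code{\link{run_design}}.
#' @param design the \code{\link{design_space}} that produced it (used for
#'   the prior ordering).
#' @param out_dir optional directory; writes \code{panels.csv} (and PDFs of
#'   the plots when available).
#' @return list with \code{table} and (possibly \code{NULL}) \code{mode_plot}
#'   and \code{entropy_plot}.
#' @export
panel_report <- function(results, design, out_dir = NULL) {
  stopifnot(inherits(design, "mfm_design"))
  ek2 <- vapply(design$priors, function(p) {
    m <- prior_moments(p)
    m[["mean"]]^2 + m[["variance"]]
  }, numeric(1))
  ord <- names(sort(ek2))
  tab <- results[results$ok, , drop = FALSE]
  tab$prior <- base::factor(tab$prior, levels = ord)
  tab <- tab[order(tab$weight_mode, tab$weight_param, tab$prior), ]
  rownames(tab) <- NULL
  mode_plot <- entropy_plot <- NULL
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    base_aes <- ggplot2::aes(x = .data$prior, colour = base::factor(.data$B0),
                             shape = base::factor(.data$C0))
    panel <- function(yvar) {
      ggplot2::ggplot(tab, base_aes) +
        ggplot2::geom_point(ggplot2::aes(y = .data[[yvar]]),
                            position = ggplot2::position_dodge(width = 0.6)) +
        ggplot2::facet_grid(weight_mode ~ weight_param) +
        ggplot2::labs(x = "prior on K (ordered by E[K^2])",
                      colour = "B0", shape = "C0", y = yvar)
    }
    mode_plot <- panel("mode")
    entropy_plot <- panel("entropy")
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "panels.csv"),
                     row.names = FALSE)
    if (!is.null(mode_plot)) {
      ggplot2::ggsave(file.path(out_dir, "mode_panels.pdf"), mode_plot,
                      width = 8, height = 5)
      ggplot2::ggsave(file.path(out_dir, "entropy_panels.pdf"), entropy_plot,
                      width = 8, height = 5)
    }
  }
  list(table = tab, mode_plot = mode_plot, entropy_plot = entropy_plot)
}
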