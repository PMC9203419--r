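# A deterministic stub sampler lets the bookkeeping be tested without MCMC
# cost: the "posterior" of K+ is a function of the cell's prior mean and C0.
stub_fit <- function(y, config) {
  m <- prior_moments(config$prior)[["mean"]]
  kp <- as.integer(1 + round(m %% 5) + (config$C0 < 1))
  structure(list(trace = data.frame(iteration = 1:4, K = kp + 1L,
                                    K_plus = rep(kp, 4)),
                 data = y), class = "mfm_fit")
}

test_that("the benchmark design enumerates 384 cells, the simulation one 96", {
  expect_equal(nrow(design_cells(benchmark_design())), 384)
  expect_equal(nrow(design_cells(simulation_design())), 96)
  d <- simulation_design()
  expect_equal(d$B0, c(6.3, 630))
  expect_equal(d$C0, c(0.5, 12.5))
  expect_equal(d$priors[["U(1,100)"]]$params$max, 100L)
})

test_that("run_design covers every cell and is deterministic", {
  y <- rnorm(30)
  des <- benchmark_design()
  r1 <- run_design(y, des, master_seed = 7, fit_fn = stub_fit)
  r2 <- run_design(y, des, master_seed = 7, fit_fn = stub_fit)
  expect_equal(nrow(r1), 384)
  expect_identical(r1, r2)
  expect_true(all(r1$ok))
})

test_that("marginal_table matches an independent group-by oracle", {
  set.seed(61)
  y <- rnorm(30)
  res <- run_design(y, benchmark_design(), master_seed = 3,
                    fit_fn = stub_fit)
  for (f in c("weight_mode", "weight_param", "prior", "B0", "C0")) {
    tab <- marginal_table(res, f)
    oracle <- tapply(res$mode, res[[f]], mean)
    expect_equal(tab$mean_mode[match(names(oracle), tab$level)],
                 as.vector(oracle), tolerance = 1e-12)
  }
  # trivial cases
  res3 <- res; res3$mode <- 3L
  expect_true(all(marginal_table(res3, "C0")$mean_mode == 3))
  expect_error(marginal_table(res[0, ], "C0"), "empty")
})

test_that("a failing cell is recorded and the run continues", {
  des <- design_space(priors = list(u = prior_k("uniform", max = 5)),
                      weight_modes = "static", weight_params = 1,
                      B0 = c(1, 2), C0 = 1)
  boom <- function(y, config) {
    if (config$B0 == 1) stop("synthetic failure") else stub_fit(y, config)
  }
  res <- run_design(rnorm(10), des, fit_fn = boom)
  expect_equal(sum(res$ok), 1)
  expect_match(res$message[!res$ok], "synthetic failure")
})

test_that("a one-cell design reproduces a direct sampler run", {
  y <- generate_dgp(benchmark_dgps()$gaussian4, seed = 70)$value
  des <- design_space(priors = list("BNB(1,4,3)" = prior_k("shifted_bnb")),
                      weight_modes = "dynamic", weight_params = 1,
                      B0 = 630, C0 = 12.5)
  mcmc <- list(n_iter = 1500, burn_in = 500, thinning = 2)
  res <- run_design(y, des, mcmc = mcmc, master_seed = 11)
  cfg <- mfm_config(prior_k("shifted_bnb"), "dynamic", 1, B0 = 630,
                    C0 = 12.5, n_iter = 1500, burn_in = 500, thinning = 2,
                    seed = res$seed[1])
  direct <- summarize_kplus(run_mfm(y, cfg))
  expect_equal(res$mode[1], direct$mode)
  expect_equal(res$entropy[1], direct$entropy)
})

test_that("runs are resumable from persisted per-cell files", {
  dir <- tempfile("cells")
  des <- design_space(priors = list(u = prior_k("uniform", max = 5)),
                      weight_modes = "static", weight_params = c(1, 10),
                      B0 = 1, C0 = c(1, 2))
  r1 <- run_design(rnorm(10), des, master_seed = 5, out_dir = dir,
                   fit_fn = stub_fit)
  expect_equal(length(list.files(dir)), 4)
  calls <- 0L
  counting <- function(y, config) { calls <<- calls + 1L; stub_fit(y, config) }
  r2 <- run_design(rnorm(10), des, master_seed = 5, out_dir = dir,
                   fit_fn = counting)
  expect_equal(calls, 0L)  # everything resumed from disk
  expect_equal(r1$mode, r2$mode)
})

test_that("panel report orders priors by the prior mean of K squared", {
  res <- run_design(rnorm(20), benchmark_design(), master_seed = 9,
                    fit_fn = stub_fit)
  rep <- panel_report(res, benchmark_design())
  expect_equal(levels(rep$table$prior),
               c("BNB(1,4,3)", "trPois(3)", "Geom(0.1)", "U(1,30)"))
  expect_equal(nrow(rep$table), 384)
})
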