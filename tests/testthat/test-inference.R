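# Priors, log posterior, MCMC machinery, diagnostics and the
# no-trafficking model variant.

make_small_dataset <- function(cv = 0, seed = 7, doses = c(0.01, 0.1, 1),
                               times = c(30, 120)) {
  cfg <- synth_config(archetypes = default_archetypes()["Treg"],
                      ligands = "IL-2", doses = doses, times = times,
                      cv = cv, seed = seed)
  sy <- synth_generate(cfg, replicates = 1)
  fit_dataset(sy$response_table, read_profiles_df(sy$receptor_table))
}

default_theta <- list(k_fwd = 0.1, k_4_rev = 5, k_endo = 0.01,
                      k_endo_active = 0.1, f_sort = 1 / 3, scale = 1)
inf_priors <- prior_spec(names(default_theta))

test_that("log posterior reduces to -N/2 log(2pi) at perfect fit, sigma 1", {
  data <- make_small_dataset(cv = 0)
  lp <- log_posterior(default_theta, data, priors = prior_spec(character(0)),
                      sigma_fixed = 1, rtol = 1e-9)
  N <- nrow(data$obs)
  expect_equal(lp, -N / 2 * log(2 * pi), tolerance = 1e-4)
})

test_that("doubling every residual multiplies the SSE term by four", {
  data <- make_small_dataset(cv = 0)
  pred <- data$obs$value           # noise-free table = model predictions
  set.seed(3)
  r <- stats::rnorm(length(pred), 0, 5)
  no_prior <- prior_spec(character(0))
  d1 <- data; d1$obs$value <- pred + r
  d2 <- data; d2$obs$value <- pred + 2 * r
  N <- nrow(data$obs)
  base <- -N / 2 * log(2 * pi)
  sse1 <- -(log_posterior(list(), d1, no_prior, sigma_fixed = 1,
                          rtol = 1e-9) - base)
  sse2 <- -(log_posterior(list(), d2, no_prior, sigma_fixed = 1,
                          rtol = 1e-9) - base)
  expect_equal(sse2 / sse1, 4, tolerance = 1e-4)
})

test_that("log posterior equals an independently coded prior + SSE sum", {
  data <- make_small_dataset(cv = 0.05, seed = 21, doses = c(0.05, 0.5))
  set.seed(5)
  theta <- list(k_fwd = 0.11, k_4_rev = 4.6, k_endo = 0.009,
                k_endo_active = 0.12, f_sort = 0.31, scale = 1.05)
  sig <- 8
  lp <- log_posterior(theta, data, inf_priors, sigma_fixed = sig,
                      rtol = 1e-9)
  # oracle: explicit prior densities + predictions via the public simulation
  # surface, assembled without the package's likelihood path
  lp_prior <- sum(
    stats::dlnorm(theta$k_fwd, log(0.1), 0.1, log = TRUE),
    stats::dlnorm(theta$k_4_rev, log(5), 0.1, log = TRUE),
    stats::dlnorm(theta$k_endo, log(0.01), 0.1, log = TRUE),
    stats::dlnorm(theta$k_endo_active, log(0.1), 0.1, log = TRUE),
    stats::dbeta(theta$f_sort, 20, 40, log = TRUE),
    stats::dlnorm(theta$scale, log(1), 0.1, log = TRUE))
  r <- default_rate_table(); r$k_fwd <- theta$k_fwd
  r$rev[["k_4_rev"]] <- theta$k_4_rev
  r <- enforce_detailed_balance(r)
  tr <- trafficking_params(k_endo = theta$k_endo,
                           k_endo_active = theta$k_endo_active,
                           f_sort = theta$f_sort)
  net <- build_network("IL-2")
  pr <- data$profiles[["Treg"]]
  syn <- synthesis_from_surface(pr$surface, tr)
  y0 <- steady_state(cell_profile("Treg", synthesis = syn), net, tr)
  sse <- 0
  for (dd in unique(data$obs$concentration_nM)) {
    rows <- data$obs[data$obs$concentration_nM == dd, ]
    trj <- simulate_protocol(y0, single_dose("IL-2", dd,
                                             sort(unique(c(0, rows$time_min)))),
                             net, r, tr, synthesis = syn, rtol = 1e-9)
    sig_t <- pstat(active_signal(trj, "IL-2"), theta$scale)
    pred <- sig_t[match(rows$time_min, trj$times)]
    sse <- sse + sum((rows$value - pred)^2)
  }
  N <- nrow(data$obs)
  lp_oracle <- lp_prior - N / 2 * log(2 * pi) - N * log(sig) -
    sse / (2 * sig^2)
  expect_equal(lp, lp_oracle, tolerance = 1e-4)
})

test_that("log posterior is invariant to observation order", {
  data <- make_small_dataset(cv = 0.05, seed = 9, doses = c(0.05, 0.5))
  set.seed(1)
  perm <- sample(nrow(data$obs))
  d2 <- data; d2$obs <- data$obs[perm, ]
  expect_equal(
    log_posterior(default_theta, data, inf_priors, sigma_fixed = 5),
    log_posterior(default_theta, d2, inf_priors, sigma_fixed = 5))
})

test_that("sampling the prior recovers its mean and sd", {
  priors <- prior_spec(c("k_fwd", "f_sort"))
  empty <- structure(list(obs = data.frame(), profiles = list()),
                     class = "gc_fitdata")
  post <- fit_mcmc(list(), priors, n_chains = 2, n_draws = 2000,
                   warmup = 1000, seed = 4)
  pooled <- rbind(post$draws[, , 1], post$draws[, , 2])
  # effective sample size from the autocorrelation time
  ess <- function(x) {
    ac <- stats::acf(x, lag.max = 100, plot = FALSE)$acf[-1]
    tau <- 1 + 2 * sum(pmax(ac[seq_len(max(which(ac > 0.05), 1))], 0))
    length(x) / tau
  }
  # lognormal(log 0.1, 0.1)
  m_true <- 0.1 * exp(0.005); s_true <- m_true * sqrt(exp(0.01) - 1)
  se <- s_true / sqrt(ess(pooled[, "k_fwd"]))
  expect_lt(abs(mean(pooled[, "k_fwd"]) - m_true), 3 * se + 1e-4)
  expect_equal(stats::sd(pooled[, "k_fwd"]), s_true, tolerance = 0.2)
  # Beta(20, 40)
  mb <- 20 / 60; sb <- sqrt(20 * 40 / (60^2 * 61))
  seb <- sb / sqrt(ess(pooled[, "f_sort"]))
  expect_lt(abs(mean(pooled[, "f_sort"]) - mb), 3 * seb + 1e-3)
  expect_equal(stats::sd(pooled[, "f_sort"]), sb, tolerance = 0.2)
})

test_that("identical seed and config give identical draws", {
  priors <- prior_spec(c("k_fwd", "k_4_rev"))
  p1 <- fit_mcmc(list(), priors, n_chains = 2, n_draws = 200, warmup = 200,
                 seed = 31)
  p2 <- fit_mcmc(list(), priors, n_chains = 2, n_draws = 200, warmup = 200,
                 seed = 31)
  expect_identical(p1$draws, p2$draws)
  expect_error(fit_mcmc(list(), priors, n_chains = 1), "2 chains")
})

test_that("Geweke diagnostic separates stationary from drifting chains", {
  expect_error(geweke(rnorm(50)), "at least 100")
  g0 <- geweke(rep(2.5, 500))
  expect_equal(unname(g0$z), 0)
  expect_true(g0$converged)

  # i.i.d. chains pass at the nominal rate
  set.seed(12)
  zs <- replicate(40, geweke(stats::rnorm(10000))$z)
  expect_gt(mean(abs(zs) < 2), 0.85)

  # a +5 sigma mean step at the midpoint is flagged
  broken <- c(stats::rnorm(5000), stats::rnorm(5000, 5))
  expect_gt(abs(geweke(broken)$z), 2)
  expect_false(geweke(broken)$converged)
})

test_that("geweke agrees with the reference implementation in coda", {
  skip_if_not_installed("coda")
  set.seed(77)
  x <- as.numeric(stats::arima.sim(list(ar = 0.6), 5000))
  z_pkg <- unname(geweke(x)$z)
  z_coda <- unname(coda::geweke.diag(coda::mcmc(x), frac1 = 0.1,
                                     frac2 = 0.5)$z)
  expect_equal(z_pkg, z_coda, tolerance = 0.15)
})

test_that("posterior bands are nested quantiles of the prediction matrix", {
  priors <- prior_spec(c("k_fwd", "scale"))
  post <- fit_mcmc(list(), priors, n_chains = 2, n_draws = 200, warmup = 200,
                   seed = 8)
  predictor <- function(th) th[["scale"]] * c(1, 2, 3)
  bands <- posterior_bands(post, predictor, n = 100,
                           quantiles = c(10, 25, 75, 90))
  preds <- attr(bands, "predictions")
  for (j in 1:3)
    expect_equal(unname(bands[j, ]),
                 unname(stats::quantile(preds[, j], c(.1, .25, .75, .9))))
  expect_true(all(bands[, "q10"] <= bands[, "q25"]))
  expect_true(all(bands[, "q75"] <= bands[, "q90"]))

  # degenerate posterior gives zero-width bands
  post0 <- post
  post0$draws[] <- 1
  b0 <- posterior_bands(post0, predictor, n = 50)
  expect_equal(unname(b0[, "q10"]), unname(b0[, "q90"]))
  expect_error(posterior_bands(post, predictor, n = 1e6), "exceeds")
})

test_that("no-trafficking variant is binding-only and surface-only", {
  tr0 <- no_trafficking()
  expect_true(trafficking_off(tr0))
  pr <- default_archetypes()$Treg
  net <- build_network("IL-2")
  y0 <- initial_state(pr, net, tr0)
  expect_true(all(y0[net$idx_endo] == 0))
  trj <- simulate_protocol(y0, single_dose("IL-2", 0.25, c(0, 5000)), net,
                           gc_default_rates, tr0)
  # endosome never populates; active signal is surface only
  expect_lt(max(trj$states[, net$idx_endo]), 1e-10)
  labs <- active_species(net, "IL-2")
  expect_equal(active_signal(trj, "IL-2"),
               rowSums(trj$states[, paste0("surf/", labs)]))
  # equilibrium signal matches the algebraic binding equilibrium
  eq <- oracle_il2_equilibrium(0.25, pr$surface[["IL-2Ra"]],
                               pr$surface[["IL-2Rb"]], pr$surface[["gc"]],
                               gc_default_rates)
  eq_active <- sum(eq[c("IL-2:IL-2Rb.gc", "IL-2:IL-2Ra.IL-2Rb.gc")])
  expect_equal(utils::tail(active_signal(trj, "IL-2"), 1), eq_active,
               tolerance = 1e-5)
})

test_that("no-trafficking fits of trafficking data need fewer receptors", {
  # data generated WITH trafficking; a binding-only refit that scales all
  # receptor abundances prefers scale < 1 (less receptor than the true
  # surface count), mirroring the variant's bias toward tiny abundances
  pr <- default_archetypes()$Treg
  doses <- c(0.01, 0.1, 1)
  truth <- gckin:::.dose_series(pr, "IL-2", doses, 60, gc_default_rates,
                                gc_default_traffic)
  sse_for <- function(s) {
    pr_s <- cell_profile("x", surface = pr$surface * s)
    pred <- gckin:::.dose_series(pr_s, "IL-2", doses, 60, gc_default_rates,
                                 no_trafficking(), rtol = 1e-7)
    sum((pred - truth)^2)
  }
  scales <- c(0.25, 0.5, 0.75, 1, 1.5)
  sses <- vapply(scales, sse_for, numeric(1))
  expect_lt(scales[which.min(sses)], 1)
})
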