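# Bayesian estimation of unknown model parameters from dose-response and
# receptor-internalization measurements.
#
# The likelihood is Gaussian on the sum of squared errors between model
# prediction and data, with one noise scale sigma per scale group (fixed, or
# fitted under a weak half-normal prior). Unknown rates and trafficking
# parameters carry lognormal priors with log-scale sd 0.1 around documented
# centers; the sorting fraction carries a Beta(20, 40) prior. Sampling uses
# an adaptive random-walk Metropolis chain on the unconstrained scale
# (log for positive parameters, logit for f_sort) with the appropriate
# Jacobian corrections, proposal covariance adapted during warm-up only.

#' Prior specification for fitted parameters
#'
#' @param params Character vector of parameter names. Recognized names:
#'   rate-table keys (`k_fwd`, `k_4_rev`, ...), trafficking fields
#'   (`k_endo`, `k_endo_active`, `f_sort`, `k_rec`, `k_deg`), pSTAT scale
#'   factors (`scale` or `scale_<group>`), and `sigma_<group>` noise scales.
#' @param centers Named numeric of prior centers; defaults come from
#'   [default_rate_table()] / [trafficking_params()] where available.
#' @param sdlog Log-scale standard deviation of the lognormal priors.
#' @return data.frame of class `gc_priors` with one row per parameter:
#'   `name`, `dist` (lognormal / beta / halfnormal), `p1`, `p2`.
#' @export
prior_spec <- function(params, centers = NULL, sdlog = 0.1) {
  if (length(params) == 0)
    return(structure(data.frame(name = character(0), dist = character(0),
                                p1 = numeric(0), p2 = numeric(0)),
                     class = c("gc_priors", "data.frame")))
  defaults <- .default_centers()
  rows <- lapply(params, function(p) {
    if (p == "f_sort")
      return(data.frame(name = p, dist = "beta", p1 = 20, p2 = 40))
    if (grepl("^sigma", p)) {
      sc <- if (!is.null(centers) && p %in% names(centers)) centers[[p]] else 1
      return(data.frame(name = p, dist = "halfnormal", p1 = sc, p2 = NA_real_))
    }
    ctr <- if (!is.null(centers) && p %in% names(centers)) centers[[p]]
           else if (p %in% names(defaults)) defaults[[p]]
           else stop("no prior center available for parameter: ", p)
    data.frame(name = p, dist = "lognormal", p1 = log(ctr), p2 = sdlog)
  })
  structure(do.call(rbind, rows), class = c("gc_priors", "data.frame"))
}

.default_centers <- function() {
  r <- default_rate_table(); tr <- trafficking_params()
  c(as.list(r$rev), list(k_fwd = r$k_fwd, k_bnd = r$k_bnd,
    k_endo = tr$k_endo, k_endo_active = tr$k_endo_active, k_rec = tr$k_rec,
    k_deg = tr$k_deg, scale = 1))
}

#' Log prior density of a parameter vector
#' @param theta Named parameter values (natural scale).
#' @param priors A `gc_priors` table.
#' @return Scalar log density (`-Inf` outside support).
#' @export
log_prior <- function(theta, priors) {
  lp <- 0
  for (i in seq_len(nrow(priors))) {
    p <- priors$name[i]; x <- theta[[p]]
    lp <- lp + switch(priors$dist[i],
      lognormal = stats::dlnorm(x, priors$p1[i], priors$p2[i], log = TRUE),
      beta = stats::dbeta(x, priors$p1[i], priors$p2[i], log = TRUE),
      halfnormal = if (x <= 0) -Inf else
        log(2) + stats::dnorm(x, 0, priors$p1[i], log = TRUE),
      stop("unknown prior family: ", priors$dist[i]))
  }
  as.numeric(lp)
}

#' Assemble a fit dataset
#'
#' @param obs data.frame with columns `cell_type`, `ligand`,
#'   `concentration_nM`, `time_min`, `readout` ("pSTAT" or
#'   "surface_fraction:<receptor>"), `value`, `replicate`, and optionally
#'   `scale_group` (defaults to the readout). pSTAT observations are related
#'   to active-complex predictions by one fitted scalar per scale group.
#' @param profiles Named list of `gc_profile`s covering all `cell_type`s.
#' @return Object of class `gc_fitdata`.
#' @export
fit_dataset <- function(obs, profiles) {
  req <- c("cell_type", "ligand", "concentration_nM", "time_min", "readout",
           "value", "replicate")
  miss <- setdiff(req, names(obs))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(obs$value))) stop("observation values must be finite")
  if (is.null(obs$scale_group)) obs$scale_group <- obs$readout
  pnames <- vapply(profiles, function(p) p$name, character(1))
  names(profiles) <- pnames
  missing_cells <- setdiff(unique(obs$cell_type), pnames)
  if (length(missing_cells) > 0)
    stop("no profile for cell type(s): ", paste(missing_cells, collapse = ", "))
  structure(list(obs = obs, profiles = profiles), class = "gc_fitdata")
}

# apply a named theta onto (rates, traffic, scales); re-enforces detailed
# balance after any rate change
.apply_theta <- function(theta, rates, traffic) {
  scales <- c(scale = 1)
  touched <- FALSE
  for (p in names(theta)) {
    v <- theta[[p]]
    if (p %in% names(rates$rev)) { rates$rev[[p]] <- v; touched <- TRUE }
    else if (p %in% c("k_fwd", "k_bnd")) { rates[[p]] <- v; touched <- TRUE }
    else if (p %in% c("k_endo", "k_endo_active", "f_sort", "k_rec", "k_deg"))
      traffic[[p]] <- v
    else if (grepl("^scale", p)) scales[[p]] <- v
    else if (!grepl("^sigma", p)) stop("unknown parameter: ", p)
  }
  if (touched) rates <- enforce_detailed_balance(rates)
  list(rates = rates, traffic = traffic, scales = scales)
}

# model predictions for every observation row; one ODE solve per
# (cell, ligand, concentration) group
.predict_obs <- function(theta, data, rates, traffic, rtol = 1e-6) {
  ap <- .apply_theta(theta, rates, traffic)
  rates <- ap$rates; traffic <- ap$traffic; scales <- ap$scales
  obs <- data$obs
  net <- build_network(unique(obs$ligand))
  pred <- numeric(nrow(obs))
  key <- interaction(obs$cell_type, obs$ligand, obs$concentration_nM,
                     drop = TRUE)
  for (g in levels(key)) {
    rows <- which(key == g)
    pr <- data$profiles[[obs$cell_type[rows[1]]]]
    syn <- if (trafficking_off(traffic)) numeric(0)
           else .profile_synthesis(pr, traffic)
    y0 <- initial_state(pr, net, traffic)
    tt <- sort(unique(c(0, obs$time_min[rows])))
    sd_ <- single_dose(obs$ligand[rows[1]], obs$concentration_nM[rows[1]], tt)
    tr <- simulate_protocol(y0, sd_, net, rates, traffic, synthesis = syn,
                            rtol = rtol, atol = 1e-4)
    for (i in rows) {
      ti <- match(obs$time_min[i], tr$times)
      ro <- obs$readout[i]
      if (ro == "pSTAT") {
        sg <- obs$scale_group[i]
        sc <- if (paste0("scale_", sg) %in% names(scales))
          scales[[paste0("scale_", sg)]] else scales[["scale"]]
        pred[i] <- pstat(active_signal(tr, obs$ligand[i]), sc)[ti]
      } else if (startsWith(ro, "surface_fraction:")) {
        pred[i] <- surface_fraction(tr, sub("^surface_fraction:", "", ro))[ti]
      } else stop("unknown readout: ", ro)
    }
  }
  pred
}

#' Log posterior of model parameters given dose-response datasets
#'
#' Gaussian likelihood built from the sum of squared errors per dataset
#' (noise scale `sigma_<group>` fitted, or fixed via `sigma_fixed`), plus the
#' log priors. Detailed balance is re-enforced at every evaluation; solver
#' failure at a parameter vector yields `-Inf` with a warning rather than an
#' error.
#'
#' @param theta Named parameter vector (natural scale).
#' @param datasets A `gc_fitdata` or list of them.
#' @param priors A `gc_priors` table.
#' @param rates,traffic Baseline model parameters that `theta` overrides.
#' @param sigma_fixed Named numeric of fixed noise scales per scale group
#'   (used for any group without a fitted `sigma_<group>` in `theta`);
#'   a single unnamed value applies to all groups.
#' @param rtol Solver relative tolerance for likelihood evaluations.
#' @return Scalar log posterior.
#' @export
log_posterior <- function(theta, datasets, priors,
                          rates = default_rate_table(),
                          traffic = trafficking_params(),
                          sigma_fixed = 1, rtol = 1e-6) {
  if (inherits(datasets, "gc_fitdata")) datasets <- list(datasets)
  lp <- log_prior(theta, priors)
  if (!is.finite(lp)) return(-Inf)
  for (d in datasets) {
    pred <- tryCatch(.predict_obs(theta, d, rates, traffic, rtol = rtol),
                     error = function(e) {
                       warning("solver failure in likelihood: ",
                               conditionMessage(e), call. = FALSE)
                       NULL
                     })
    if (is.null(pred)) return(-Inf)
    for (g in unique(d$obs$scale_group)) {
      rows <- d$obs$scale_group == g
      sse <- sum((d$obs$value[rows] - pred[rows])^2)
      sig_name <- paste0("sigma_", g)
      sig <- if (sig_name %in% names(theta)) theta[[sig_name]]
             else if (!is.null(names(sigma_fixed)) && g %in% names(sigma_fixed))
               sigma_fixed[[g]]
             else sigma_fixed[[1]]
      n <- sum(rows)
      lp <- lp - n / 2 * log(2 * pi) - n * log(sig) - sse / (2 * sig^2)
    }
  }
  as.numeric(lp)
}

# unconstrained transform per prior family
.to_unconstrained <- function(theta, priors) {
  z <- theta
  for (i in seq_len(nrow(priors))) {
    p <- priors$name[i]
    z[[p]] <- if (priors$dist[i] == "beta") stats::qlogis(theta[[p]])
              else log(theta[[p]])
  }
  z
}
.to_natural <- function(z, priors) {
  theta <- z
  for (i in seq_len(nrow(priors))) {
    p <- priors$name[i]
    theta[[p]] <- if (priors$dist[i] == "beta") stats::plogis(z[[p]])
                  else exp(z[[p]])
  }
  theta
}
.log_jacobian <- function(z, priors) {
  lj <- 0
  for (i in seq_len(nrow(priors))) {
    p <- priors$name[i]
    lj <- lj + if (priors$dist[i] == "beta")
      stats::plogis(z[[p]], log.p = TRUE) +
        stats::plogis(-z[[p]], log.p = TRUE)
    else z[[p]]
  }
  as.numeric(lj)
}

#' Fit unknown parameters by Markov chain Monte Carlo
#'
#' Adaptive random-walk Metropolis on the unconstrained scale. The proposal
#' covariance is adapted from the accumulated history during warm-up (scaled
#' 2.38^2/d with a small diagonal regularizer) and frozen afterwards, so the
#' post-warm-up chain is a valid Metropolis sampler. Reproducible given
#' `seed`; chains are independent restarts with distinct sub-seeds.
#'
#' @param datasets A `gc_fitdata` or list of them (may be empty-`obs` to
#'   sample the prior).
#' @param priors A `gc_priors` table (defines the fitted parameters).
#' @param n_chains Number of chains (>= 2 for diagnostics).
#' @param n_draws Retained post-warm-up draws per chain.
#' @param warmup Warm-up iterations (default `n_draws`, i.e. 50 percent).
#' @param thin Keep every `thin`-th post-warm-up iteration (default 1);
#'   `n_draws * thin` iterations are run after warm-up.
#' @param seed Integer seed.
#' @param init Named starting values (default: prior centers).
#' @param ... Passed to [log_posterior()] (`rates`, `traffic`,
#'   `sigma_fixed`, `rtol`).
#' @return Object of class `gc_posterior`: `draws` (n_draws x n_params x
#'   n_chains array, natural scale), `log_post`, `accept_rate`, `seed`.
#' @export
fit_mcmc <- function(datasets, priors, n_chains = 2, n_draws = 1000,
                     warmup = n_draws, thin = 1, seed = 1, init = NULL, ...) {
  if (n_chains < 2) stop("at least 2 chains are required for diagnostics")
  pn <- priors$name
  d <- length(pn)
  centers <- vapply(pn, function(p) switch(priors$dist[match(p, priors$name)],
      lognormal = exp(priors$p1[match(p, priors$name)]),
      beta = priors$p1[match(p, priors$name)] /
        (priors$p1[match(p, priors$name)] + priors$p2[match(p, priors$name)]),
      halfnormal = priors$p1[match(p, priors$name)] * sqrt(2 / pi)),
    numeric(1))
  if (!is.null(init)) centers[names(init)] <- init
  lp_fun <- function(z) {
    theta <- .to_natural(z, priors)
    lp <- log_posterior(theta, datasets, priors, ...)
    if (!is.finite(lp)) return(-Inf)
    lp + .log_jacobian(z, priors)
  }
  draws <- array(NA_real_, dim = c(n_draws, d, n_chains),
                 dimnames = list(NULL, pn, NULL))
  logp <- matrix(NA_real_, n_draws, n_chains)
  acc <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed * 1000L + ch)
    z <- .to_unconstrained(stats::setNames(as.list(centers), pn), priors)
    z <- unlist(z)[pn]
    # jitter starts so chains are over-dispersed relative to the posterior
    z <- z + stats::rnorm(d, 0, 0.02)
    lp <- lp_fun(z)
    if (!is.finite(lp)) stop("initial point has zero posterior density")
    cov_p <- diag(0.03^2, d)
    chol_p <- chol(cov_p)
    hist_z <- matrix(NA_real_, warmup, d)
    n_acc <- 0L
    total <- warmup + n_draws * thin
    for (it in seq_len(total)) {
      zprop <- z + as.vector(stats::rnorm(d) %*% chol_p)
      lpp <- lp_fun(zprop)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        z <- zprop; lp <- lpp
        if (it > warmup) n_acc <- n_acc + 1L
      }
      if (it <= warmup) {
        hist_z[it, ] <- z
        if (it >= 50 && it %% 25 == 0) {
          emp <- stats::cov(hist_z[seq_len(it), , drop = FALSE])
          cov_p <- 2.38^2 / d * emp + diag(1e-8, d)
          chol_p <- tryCatch(chol(cov_p), error = function(e) chol_p)
        }
      } else if ((it - warmup) %% thin == 0) {
        k <- (it - warmup) %/% thin
        draws[k, , ch] <- unlist(.to_natural(
          stats::setNames(as.list(z), pn), priors))[pn]
        logp[k, ch] <- lp
      }
    }
    acc[ch] <- n_acc / (n_draws * thin)
  }
  structure(list(draws = draws, log_post = logp, accept_rate = acc,
                 priors = priors, seed = seed,
                 config = list(n_chains = n_chains, n_draws = n_draws,
                               warmup = warmup, thin = thin)),
            class = "gc_posterior")
}

#' @exportS3Method print gc_posterior
print.gc_posterior <- function(x, ...) {
  cat(sprintf("gc posterior: %d chains x %d draws, %d parameters\n",
              dim(x$draws)[3], dim(x$draws)[1], dim(x$draws)[2]))
  cat("acceptance:", paste(sprintf("%.2f", x$accept_rate), collapse = ", "),
      "\n")
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior summary table
#' @param samples A `gc_posterior`.
#' @return data.frame with median, 10/25/75/90 percent quantiles and Geweke z
#'   per parameter (chains pooled; Geweke on chain 1).
#' @export
posterior_summary <- function(samples) {
  pn <- dimnames(samples$draws)[[2]]
  pooled <- do.call(rbind, lapply(seq_len(dim(samples$draws)[3]),
                                  function(ch) samples$draws[, , ch]))
  if (length(pn) == 1) pooled <- matrix(pooled, ncol = 1,
                                        dimnames = list(NULL, pn))
  gz <- geweke(samples$draws[, , 1, drop = FALSE][, , 1])
  q <- t(apply(pooled, 2, stats::quantile, c(0.1, 0.25, 0.5, 0.75, 0.9)))
  data.frame(parameter = pn, median = q[, 3], q10 = q[, 1], q25 = q[, 2],
             q75 = q[, 4], q90 = q[, 5], geweke_z = gz$z, row.names = NULL)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first fraction of a chain with the mean of the
#' last fraction, standardizing by spectral-density variance estimates:
#' `z = (m1 - m2) / sqrt(s1/n1 + s2/n2)` with `s` the spectral density at
#' frequency zero (autoregressive estimator). A chain is flagged converged
#' when all |z| < 2. Zero-variance (constant) chains return z = 0.
#'
#' @param chain Numeric vector or matrix (iterations x parameters).
#' @param first,last Fractions of the chain to compare (defaults 0.1, 0.5).
#' @return List with `z` (per parameter) and `converged`.
#' @export
geweke <- function(chain, first = 0.1, last = 0.5) {
  if (is.null(dim(chain))) chain <- matrix(chain, ncol = 1)
  n <- nrow(chain)
  if (n < 100) stop("chain length must be at least 100")
  i1 <- seq_len(floor(first * n))
  i2 <- seq.int(n - floor(last * n) + 1, n)
  z <- vapply(seq_len(ncol(chain)), function(j) {
    x1 <- chain[i1, j]; x2 <- chain[i2, j]
    if (stats::var(chain[, j]) == 0) return(0)
    s1 <- .spectrum0(x1); s2 <- .spectrum0(x2)
    denom <- sqrt(s1 / length(x1) + s2 / length(x2))
    if (denom == 0) return(0)
    (mean(x1) - mean(x2)) / denom
  }, numeric(1))
  names(z) <- colnames(chain)
  list(z = z, converged = all(abs(z) < 2))
}

# spectral density at frequency zero via an AIC-selected AR fit
.spectrum0 <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- tryCatch(stats::ar(x, aic = TRUE,
                            order.max = min(30, floor(length(x) / 4))),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Pointwise posterior predictive bands
#'
#' Applies a predictor to a subset of posterior draws and returns pointwise
#' quantile bands.
#'
#' @param samples A `gc_posterior`.
#' @param predictor Function taking a named parameter vector and returning a
#'   numeric prediction vector.
#' @param n Number of draws to use (default 100; taken evenly spaced through
#'   the pooled chains for reproducibility).
#' @param quantiles Band quantiles (percent).
#' @return Matrix (length(prediction) x length(quantiles)) of pointwise
#'   quantiles, with the prediction matrix in attribute `"predictions"`.
#' @export
posterior_bands <- function(samples, predictor, n = 100,
                            quantiles = c(10, 25, 75, 90)) {
  pooled <- do.call(rbind, lapply(seq_len(dim(samples$draws)[3]),
                                  function(ch) samples$draws[, , ch]))
  pn <- dimnames(samples$draws)[[2]]
  if (length(pn) == 1) pooled <- matrix(pooled, ncol = 1,
                                        dimnames = list(NULL, pn))
  if (n > nrow(pooled)) stop("n exceeds the number of available draws")
  idx <- unique(round(seq(1, nrow(pooled), length.out = n)))
  preds <- t(vapply(idx, function(i) {
    th <- stats::setNames(as.numeric(pooled[i, ]), pn)
    predictor(th)
  }, predictor(stats::setNames(as.numeric(pooled[1, ]), pn))))
  bands <- apply(preds, 2, stats::quantile, probs = quantiles / 100)
  bands <- t(matrix(bands, nrow = length(quantiles),
                    dimnames = list(paste0("q", quantiles), NULL)))
  attr(bands, "predictions") <- preds
  bands
}

#' Export posterior draws and summary to CSV
#' @param samples A `gc_posterior`.
#' @param path_draws,path_summary Output CSV paths.
#' @return Invisibly, the summary data.frame.
#' @export
write_posterior <- function(samples, path_draws, path_summary) {
  pn <- dimnames(samples$draws)[[2]]
  rows <- do.call(rbind, lapply(seq_len(dim(samples$draws)[3]), function(ch) {
    df <- as.data.frame(samples$draws[, , ch, drop = FALSE][, , 1])
    names(df) <- pn
    df$chain <- ch
    df$draw <- seq_len(nrow(df))
    df
  }))
  utils::write.csv(rows, path_draws, row.names = FALSE)
  sm <- posterior_summary(samples)
  utils::write.csv(sm, path_summary, row.names = FALSE)
  invisible(sm)
}
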