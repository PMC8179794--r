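# Dose-response summaries (Hill EC50), regulatory T cell specificity,
# sensitivity of specificity to surface/endosomal reverse rates, and
# engineered-ligand (mutein) affinity overrides.

#' Fit a Hill dose-response curve
#'
#' Unbounded nonlinear least squares of
#' `response = baseline + amplitude * dose^n / (EC50^n + dose^n)`.
#' Fits are unbounded, so a negative fitted baseline is reported as-is
#' rather than clipped.
#'
#' @param doses Dose vector (>= 4 distinct values).
#' @param responses Response vector (same length).
#' @return Object of class `gc_hill`: `EC50`, `hill`, `amplitude`,
#'   `baseline`, `residual_norm`, `fitted`.
#' @examples
#' d <- 10^seq(-3, 2, length.out = 8)
#' y <- 100 * d / (1 + d)
#' fit_hill(d, y)$EC50   # ~1
#' @export
fit_hill <- function(doses, responses) {
  if (length(unique(doses)) < 4) stop("need at least 4 distinct doses")
  if (length(doses) != length(responses)) stop("length mismatch")
  df <- data.frame(d = doses, y = responses)
  b0 <- min(responses); a0 <- max(responses) - b0
  if (a0 <= 0) a0 <- max(abs(responses), 1e-6)
  half <- b0 + a0 / 2
  e0 <- doses[which.min(abs(responses - half))]
  if (e0 <= 0) e0 <- stats::median(doses[doses > 0])
  starts <- list(
    c(le = log(e0), n = 1, A = a0, b = b0),
    c(le = log(stats::median(doses[doses > 0])), n = 1.5, A = a0, b = 0),
    c(le = log(max(doses) / 10), n = 0.7, A = a0, b = b0)
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ b + A * d^n / (exp(le)^n + d^n), data = df,
      start = as.list(st),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rn <- sqrt(sum(stats::resid(fit)^2))
      if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
    }
  }
  if (is.null(best))
    stop("Hill fit did not converge; data summary: range [",
         signif(min(responses), 3), ", ", signif(max(responses), 3),
         "], monotone = ", !is.unsorted(responses[order(doses)]))
  cf <- stats::coef(best$fit)
  structure(list(EC50 = exp(cf[["le"]]), hill = cf[["n"]],
                 amplitude = cf[["A"]], baseline = cf[["b"]],
                 residual_norm = best$rn,
                 fitted = stats::fitted(best$fit)), class = "gc_hill")
}

#' @exportS3Method print gc_hill
print.gc_hill <- function(x, ...) {
  cat(sprintf("Hill fit: EC50 = %.4g nM, n = %.3g, amplitude = %.4g, baseline = %.4g\n",
              x$EC50, x$hill, x$amplitude, x$baseline))
  invisible(x)
}

#' Cell-type signaling specificity
#'
#' The ratio of the target cell's pSTAT response to an off-target cell's
#' response at a stated dose and time. Responses are normalized per cell to
#' that cell's maximum over the supplied frame (set `normalize = "none"` for
#' raw ratios); the pSTAT scale factor cancels either way.
#'
#' @param responses data.frame with columns `cell_type`, `concentration_nM`,
#'   `time_min`, `value` (one ligand's responses).
#' @param target,off_target Cell-type labels.
#' @param dose_nM,time_min Condition at which the ratio is taken (defaults
#'   0.038 nM, 60 min).
#' @param normalize "max" (per-cell maximum) or "none".
#' @return One-row data.frame: target, off_target, dose, time, specificity.
#' @export
specificity <- function(responses, target, off_target, dose_nM = 0.038,
                        time_min = 60, normalize = c("max", "none")) {
  normalize <- match.arg(normalize)
  need <- c("cell_type", "concentration_nM", "time_min", "value")
  miss <- setdiff(need, names(responses))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  val <- function(cell) {
    rows <- responses$cell_type == cell
    if (!any(rows)) stop("no responses for cell type: ", cell)
    v <- responses$value[rows & responses$concentration_nM == dose_nM &
                           responses$time_min == time_min]
    if (length(v) == 0)
      stop("no response at dose ", dose_nM, " nM / ", time_min,
           " min for ", cell)
    v <- mean(v)
    if (normalize == "max") {
      mx <- max(responses$value[rows])
      v <- if (mx > 0) v / mx else 0
    }
    v
  }
  tv <- val(target); ov <- val(off_target)
  if (ov <= 0) stop("off-target response is zero; specificity undefined")
  data.frame(target = target, off_target = off_target, dose_nM = dose_nM,
             time_min = time_min, specificity = tv / ov)
}

# simulate one cell's pSTAT dose series for a ligand (helper shared by the
# specificity machinery)
.dose_series <- function(profile, ligand, doses, time_min, rates, traffic,
                         rtol = 1e-8) {
  net <- build_network(ligand)
  syn <- if (trafficking_off(traffic)) numeric(0)
         else .profile_synthesis(profile, traffic)
  y0 <- initial_state(profile, net, traffic)
  vapply(doses, function(dd) {
    tr <- simulate_protocol(y0, single_dose(ligand, dd, c(0, time_min)),
                            net, rates, traffic, synthesis = syn, rtol = rtol,
                            atol = 1e-6)
    utils::tail(active_signal(tr, ligand), 1)
  }, numeric(1))
}

#' Model-predicted specificity between two cell profiles
#'
#' Simulates both profiles across a dose series, normalizes each cell by its
#' maximum over the series, and returns the target/off-target ratio at the
#' stated dose and time.
#'
#' @param profiles Named list of `gc_profile`s including target and
#'   off-target.
#' @param target,off_target Profile names.
#' @param ligand Stimulating ligand.
#' @param dose_nM,time_min Evaluation condition.
#' @param doses Dose series over which the per-cell maximum is taken (must
#'   contain `dose_nM`).
#' @param rates,traffic Model parameters.
#' @return One-row data.frame as in [specificity()].
#' @export
predict_specificity <- function(profiles, target, off_target, ligand = "IL-2",
                                dose_nM = 0.038, time_min = 60,
                                doses = c(0.001, 0.01, 0.038, 0.38, 3.8, 38),
                                rates = default_rate_table(),
                                traffic = trafficking_params()) {
  if (!dose_nM %in% doses) doses <- sort(c(doses, dose_nM))
  resp <- do.call(rbind, lapply(c(target, off_target), function(cn) {
    pr <- profiles[[cn]]
    if (is.null(pr)) stop("no profile named ", cn)
    data.frame(cell_type = cn, concentration_nM = doses, time_min = time_min,
               value = .dose_series(pr, ligand, doses, time_min, rates,
                                    traffic))
  }))
  specificity(resp, target, off_target, dose_nM, time_min)
}

#' Sensitivity of specificity to reverse binding rates
#'
#' Derivative of the target/off-target specificity with respect to the
#' natural log of each reverse rate, varied in the surface or the endosomal
#' compartment independently. Central finite differences with relative step
#' `h` (default 1e-2), cross-checked against step `h/10`; disagreement beyond
#' 1 percent triggers a warning carrying both estimates. Each rate is
#' perturbed individually (detailed balance is not re-imposed, so the
#' sensitivity isolates that one rate).
#'
#' @param profiles Named list of `gc_profile`s.
#' @param target,off_target Profile names.
#' @param ligand Stimulating ligand.
#' @param rate_keys Reverse-rate keys to differentiate (default: every
#'   reverse rate of the ligand's network).
#' @param compartment "surface" or "endosome".
#' @param dose_nM,time_min Evaluation condition.
#' @param doses Dose series for per-cell normalization.
#' @param rates,traffic Model parameters.
#' @param h Log-scale step.
#' @return data.frame: `rate`, `compartment`, `derivative`, `derivative_check`.
#' @export
specificity_gradient <- function(profiles, target, off_target,
                                 ligand = "IL-2", rate_keys = NULL,
                                 compartment = c("surface", "endosome"),
                                 dose_nM = 0.038, time_min = 60,
                                 doses = c(0.0038, 0.038, 0.38, 3.8, 38),
                                 rates = default_rate_table(),
                                 traffic = trafficking_params(), h = 1e-2) {
  compartment <- match.arg(compartment)
  net <- build_network(ligand)
  if (is.null(rate_keys)) rate_keys <- unique(net$reactions$key)
  if (any(rates$rev[intersect(rate_keys, names(rates$rev))] <= 0))
    stop("rates must be positive")
  # materialize endosomal overrides so compartments vary independently
  if (is.null(rates$endo_rev)) rates$endo_rev <- rates$rev
  spec_at <- function(r) predict_specificity(
    profiles, target, off_target, ligand, dose_nM, time_min, doses,
    rates = r, traffic = traffic)$specificity
  perturb <- function(key, lstep) {
    r <- rates
    if (compartment == "surface") r$rev[[key]] <- r$rev[[key]] * exp(lstep)
    else r$endo_rev[[key]] <- r$endo_rev[[key]] * exp(lstep)
    r
  }
  out <- lapply(rate_keys, function(key) {
    if (!key %in% names(rates$rev))
      return(data.frame(rate = key, compartment = compartment,
                        derivative = 0, derivative_check = 0))
    grad <- function(hh)
      (spec_at(perturb(key, hh)) - spec_at(perturb(key, -hh))) / (2 * hh)
    d1 <- grad(h); d2 <- grad(h / 10)
    ref <- max(abs(d1), abs(d2))
    if (ref > 1e-8 && abs(d1 - d2) > 0.01 * ref)
      warning(sprintf(
        "finite-difference check failed for %s (%s): %.6g vs %.6g",
        key, compartment, d1, d2), call. = FALSE)
    data.frame(rate = key, compartment = compartment, derivative = d2,
               derivative_check = d1)
  })
  do.call(rbind, out)
}

#' Define an engineered IL-2 variant (mutein) by its measured affinities
#'
#' @param name Mutein label.
#' @param kd_il2ra_nM Dissociation constant for IL-2Ra (nM).
#' @param kd_il2rbg_nM Dissociation constant for the pre-dimerized
#'   IL-2Rb/gc heterodimer (nM).
#' @param fc_orientation "N-terminal", "C-terminal" or "none".
#' @return Object of class `gc_mutein`.
#' @export
mutein_spec <- function(name, kd_il2ra_nM, kd_il2rbg_nM,
                        fc_orientation = c("none", "N-terminal", "C-terminal")) {
  if (kd_il2ra_nM <= 0 || kd_il2rbg_nM <= 0) stop("KDs must be positive")
  structure(list(name = name, kd_il2ra_nM = kd_il2ra_nM,
                 kd_il2rbg_nM = kd_il2rbg_nM,
                 fc_orientation = match.arg(fc_orientation)),
            class = "gc_mutein")
}

#' Apply a mutein's measured affinities to the IL-2 rate constants
#'
#' The IL-2Ra affinity change maps directly onto the ligand-IL-2Ra
#' dissociation rate (`k_1_rev` scaled by KD_a / KD_a,wt). The composite
#' IL-2Rb/gc affinity is measured against a pre-dimerized heterodimer, so its
#' fold-change is applied uniformly to the IL-2Rb binding and gc-dimerization
#' reverse rates (`k_2_rev`, `k_4_rev`, `k_5_rev`, `k_10_rev`). Detailed
#' balance is re-enforced afterwards, propagating the changes to the
#' dependent rates.
#'
#' @param rates A `gc_rates` table (wild-type).
#' @param spec A `gc_mutein`.
#' @param wildtype_KDs List/vector with `kd_il2ra_nM` and `kd_il2rbg_nM` of
#'   the wild-type ligand in the same assay.
#' @return Updated, rebalanced `gc_rates`.
#' @export
apply_mutein <- function(rates, spec, wildtype_KDs) {
  stopifnot(inherits(spec, "gc_mutein"))
  wt_a <- wildtype_KDs[["kd_il2ra_nM"]]
  wt_bg <- wildtype_KDs[["kd_il2rbg_nM"]]
  if (is.null(wt_a) || is.null(wt_bg) || wt_a <= 0 || wt_bg <= 0)
    stop("wild-type KDs must be positive")
  fold_a <- spec$kd_il2ra_nM / wt_a
  fold_bg <- spec$kd_il2rbg_nM / wt_bg
  keys_bg <- c("k_2_rev", "k_4_rev", "k_5_rev", "k_10_rev")
  scale_one <- function(v) {
    v[["k_1_rev"]] <- v[["k_1_rev"]] * fold_a
    v[keys_bg] <- v[keys_bg] * fold_bg
    v
  }
  rates$rev <- scale_one(rates$rev)
  if (!is.null(rates$endo_rev)) rates$endo_rev <- scale_one(rates$endo_rev)
  enforce_detailed_balance(rates)
}

#' Read a mutein panel from CSV
#'
#' Columns: `name`, `kd_il2ra_nM`, `kd_il2rbg_nM`, `fc_orientation`. A small
#' synthetic example panel (invented values illustrating that N-terminal Fc
#' fusion weakens IL-2Rb/gc binding while C-terminal fusion weakens IL-2Ra
#' binding) ships at
#' `system.file("extdata", "muteins_synthetic.csv", package = "gckin")`.
#'
#' @param path CSV path.
#' @return Named list of `gc_mutein`s.
#' @export
read_mutein_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "kd_il2ra_nM", "kd_il2rbg_nM", "fc_orientation")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    if (df$kd_il2ra_nM[i] <= 0 || df$kd_il2rbg_nM[i] <= 0)
      stop("non-positive KD at row ", i)
    mutein_spec(df$name[i], df$kd_il2ra_nM[i], df$kd_il2rbg_nM[i],
                df$fc_orientation[i])
  })
  stats::setNames(out, df$name)
}
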