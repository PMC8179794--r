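# Cell profiles, no-ligand steady state, protocol integration and readouts.

#' Define a cell profile by receptor synthesis rates or surface abundances
#'
#' A cell type is characterized by its receptor expression. Either constant
#' synthesis rates (#/cell/min) or measured surface abundances (#/cell) may
#' be given; abundances are converted to synthesis rates with
#' [synthesis_from_surface()] under the no-ligand steady-state assumption.
#'
#' @param name Cell-type label.
#' @param synthesis Named non-negative vector of per-receptor synthesis rates.
#' @param surface Named non-negative vector of surface abundances.
#' @return Object of class `gc_profile`.
#' @export
cell_profile <- function(name, synthesis = NULL, surface = NULL) {
  if (is.null(synthesis) && is.null(surface))
    stop("provide synthesis rates or surface abundances")
  for (v in list(synthesis, surface))
    if (!is.null(v) && (is.null(names(v)) || any(v < 0)))
      stop("receptor vectors must be named and non-negative")
  structure(list(name = name, synthesis = synthesis, surface = surface),
            class = "gc_profile")
}

# closed-form no-ligand steady state of the two trafficking equations for a
# single inactive free receptor with constant synthesis v:
#   E = v * (k_rec(1-f) + k_deg f) / (k_endo * k_deg * f)
#   I = k_endo * E / (phi * (k_rec(1-f) + k_deg f))
.ss_denominator <- function(traffic) {
  traffic$k_rec * (1 - traffic$f_sort) + traffic$k_deg * traffic$f_sort
}

#' No-ligand steady state of a cell
#'
#' In the absence of ligand all complexes are zero and each free receptor
#' independently balances synthesis, endocytosis, recycling and degradation.
#' The closed-form fixed point is returned as a full system state.
#'
#' With the no-trafficking variant (all trafficking rates zero) steady state
#' only exists for zero synthesis; supply surface abundances via
#' [initial_state()] instead.
#'
#' @param profile A `gc_profile` carrying synthesis rates (surface abundances
#'   are converted automatically).
#' @param network A `gc_network`.
#' @param traffic A `gc_traffic` parameter set.
#' @return Named state vector (surface and endosomal free receptors set,
#'   everything else zero).
#' @examples
#' tr <- trafficking_params(k_endo = 0.08, f_sort = 1/3, k_rec = 0.1,
#'                          k_deg = 0.01)
#' net <- build_network("IL-2")
#' pr <- cell_profile("x", synthesis = c("IL-2Rb" = 1))
#' steady_state(pr, net, tr)[["surf/IL-2Rb"]]  # 262.5
#' @export
steady_state <- function(profile, network, traffic) {
  syn <- profile$synthesis
  if (is.null(syn))
    syn <- synthesis_from_surface(profile$surface, traffic)
  syn <- syn[names(syn) %in% network$receptors]
  y <- empty_state(network)
  if (length(syn) == 0 || all(syn == 0)) return(y)
  D <- .ss_denominator(traffic)
  if (traffic$k_endo <= 0 || traffic$k_deg * traffic$f_sort <= 0)
    stop("no finite no-ligand steady state: receptor synthesis with zero ",
         "endocytosis or degradation accumulates without bound")
  E <- syn * D / (traffic$k_endo * traffic$k_deg * traffic$f_sort)
  I <- traffic$k_endo * E / (traffic$phi * D)
  ii <- match(names(syn), network$species$label)
  y[network$idx_surf[ii]] <- E
  y[network$idx_endo[ii]] <- I
  y
}

#' Solve receptor synthesis rates from measured surface abundances
#'
#' Exact inverse of the [steady_state()] closed form, per receptor:
#' `v = E * k_endo * k_deg * f_sort / (k_rec(1-f_sort) + k_deg f_sort)`.
#' With trafficking off, synthesis is zero and abundances are constants.
#'
#' @param surface Named non-negative surface abundances (#/cell).
#' @param traffic A `gc_traffic` parameter set.
#' @return Named synthesis rates (#/cell/min).
#' @export
synthesis_from_surface <- function(surface, traffic) {
  if (any(surface < 0)) stop("surface abundances must be non-negative")
  if (trafficking_off(traffic)) return(surface * 0)
  D <- .ss_denominator(traffic)
  surface * traffic$k_endo * traffic$k_deg * traffic$f_sort / D
}

#' Initial state for a cell under either model variant
#'
#' With trafficking on, the no-ligand steady state; with the no-trafficking
#' variant, surface abundances placed directly on the surface (endosome
#' empty, no turnover).
#'
#' @inheritParams steady_state
#' @return Named state vector.
#' @export
initial_state <- function(profile, network, traffic) {
  if (trafficking_off(traffic)) {
    surf <- profile$surface
    if (is.null(surf))
      stop("the no-trafficking variant needs surface abundances")
    surf <- surf[names(surf) %in% network$receptors]
    y <- empty_state(network)
    y[network$idx_surf[match(names(surf), network$species$label)]] <- surf
    return(y)
  }
  steady_state(profile, network, traffic)
}

#' Stimulation protocol
#'
#' @param events data.frame with columns `ligand`, `concentration_nM`,
#'   `onset_min` (non-decreasing onsets, non-negative concentrations). Each
#'   event clamps that ligand's extracellular concentration from its onset
#'   onward.
#' @param t_grid Output times (min), strictly increasing, starting at 0.
#' @return Object of class `gc_protocol`.
#' @export
protocol <- function(events, t_grid) {
  stopifnot(is.data.frame(events),
            all(c("ligand", "concentration_nM", "onset_min") %in% names(events)))
  if (nrow(events) > 1 && is.unsorted(events$onset_min))
    stop("event onset times must be non-decreasing")
  if (any(events$concentration_nM < 0)) stop("concentrations must be >= 0")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  structure(list(events = events, t_grid = t_grid), class = "gc_protocol")
}

#' Single-ligand stimulation from time zero
#' @param ligand Ligand identifier.
#' @param concentration_nM Dose (nM).
#' @param t_grid Output times (min).
#' @return A `gc_protocol`.
#' @export
single_dose <- function(ligand, concentration_nM, t_grid) {
  protocol(data.frame(ligand = ligand, concentration_nM = concentration_nM,
                      onset_min = 0), t_grid)
}

#' Integrate a stimulation protocol
#'
#' Stiff integration (deSolve's lsoda) of the full binding + trafficking
#' system, restarted at each stimulus onset with the corresponding
#' extracellular ligand clamped to its new concentration.
#'
#' @param state0 Initial state (typically from [steady_state()]).
#' @param prot A `gc_protocol`.
#' @param network,rates,traffic Model definition.
#' @param synthesis Named receptor synthesis rates (#/cell/min).
#' @param rtol,atol Solver tolerances (defaults 1e-9 relative).
#' @return Object of class `gc_trajectory`: `times`, `states` (time x state
#'   matrix), `network`, and solver `diagnostics`.
#' @export
simulate_protocol <- function(state0, prot, network, rates, traffic,
                              synthesis = numeric(0), rtol = 1e-9,
                              atol = 1e-6) {
  stopifnot(inherits(prot, "gc_protocol"))
  ev <- make_rhs(network, rates, traffic, synthesis)
  gc_set_model(ev$P)   # hand the model block to the compiled derivs entry
  t_grid <- prot$t_grid
  t_end <- max(t_grid)
  onsets <- unique(prot$events$onset_min)
  bounds <- sort(unique(c(0, onsets[onsets < t_end], t_end)))
  y <- unname(state0)
  out_t <- numeric(0); out_y <- NULL
  if (0 %in% t_grid) { out_t <- 0; out_y <- matrix(y, nrow = 1) }
  n_steps <- 0L
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    evk <- prot$events[prot$events$onset_min == t0, , drop = FALSE]
    for (j in seq_len(nrow(evk)))
      y[network$idx_xlig[[evk$ligand[j]]]] <- evk$concentration_nM[j]
    tt <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid <= t1], t1)))
    sol <- deSolve::lsoda(y = y, times = tt, func = "gc_derivs",
                          dllname = "gckin", initfunc = NULL, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop("solver failure near t = ", utils::tail(sol[, 1], 1), " min")
    n_steps <- n_steps + attr(sol, "istate")[15]
    keep <- sol[, 1] %in% t_grid & sol[, 1] > t0
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
    y <- sol[nrow(sol), -1]
  }
  states <- pmax(out_y, 0)  # clip solver noise at the non-negativity boundary
  colnames(states) <- network$state_names
  structure(list(times = out_t, states = states, network = network,
                 traffic = traffic,
                 diagnostics = list(rtol = rtol, atol = atol, steps = n_steps)),
            class = "gc_trajectory")
}

#' @exportS3Method print gc_trajectory
print.gc_trajectory <- function(x, ...) {
  cat(sprintf("gc trajectory: %d time points over %g min, %d states\n",
              length(x$times), max(x$times), ncol(x$states)))
  invisible(x)
}

#' Active signaling complexes over time
#'
#' Sums, per time point, all active complexes of a ligand over both
#' compartments; endosomal species count as `phi` times their
#' area-normalized abundance (total molecules).
#'
#' @param traj A `gc_trajectory`.
#' @param ligand Ligand in the trajectory's network.
#' @param endosomal_weight Weight on endosomal active complexes (default 1,
#'   i.e. endosomal complexes signal like surface ones).
#' @return Numeric vector (#/cell per time point).
#' @export
active_signal <- function(traj, ligand, endosomal_weight = 1) {
  net <- traj$network
  if (!ligand %in% net$ligands) stop("ligand not in network: ", ligand)
  ii <- net$active_by_ligand[[ligand]]
  if (length(ii) == 0) return(numeric(length(traj$times)))
  surf <- traj$states[, net$idx_surf[ii], drop = FALSE]
  endo <- traj$states[, net$idx_endo[ii], drop = FALSE]
  phi <- traj$traffic$phi
  rowSums(surf) + endosomal_weight * phi * rowSums(endo)
}

#' Scale active complexes to a pSTAT prediction
#'
#' The model's output is the number of active complexes; measured STAT
#' phosphorylation (pSTAT5 for IL-2/-7/-9/-15/-21 complexes, pSTAT6 for
#' IL-4) is related to it by a fitted scalar.
#'
#' @param active Numeric active-complex series.
#' @param scale Positive scalar.
#' @return `scale * active`.
#' @export
pstat <- function(active, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("pSTAT scale must be a positive scalar")
  scale * active
}

#' Surface abundance of a receptor chain as percent of initial
#'
#' Totals the chain over all surface species containing it (free and
#' complexed) and reports 100 x total(t) / total(0).
#'
#' @param traj A `gc_trajectory`.
#' @param receptor Chain name (e.g. "IL-2Rb", "gc").
#' @return Numeric percent series.
#' @export
surface_fraction <- function(traj, receptor) {
  net <- traj$network
  if (!receptor %in% net$receptors) stop("unknown receptor: ", receptor)
  w <- net$chain_matrix[receptor, ]
  tot <- as.vector(traj$states[, net$idx_surf, drop = FALSE] %*% w)
  if (tot[1] <= 0) stop("zero initial surface abundance of ", receptor)
  100 * tot / tot[1]
}

#' Total abundance of a chain over all species (conservation bookkeeping)
#'
#' surface + phi x endosomal, summed over every species containing the chain.
#'
#' @param traj A `gc_trajectory`.
#' @param receptor Chain name.
#' @return Numeric series (#/cell).
#' @export
chain_total <- function(traj, receptor) {
  net <- traj$network
  w <- net$chain_matrix[receptor, ]
  surf <- as.vector(traj$states[, net$idx_surf, drop = FALSE] %*% w)
  endo <- as.vector(traj$states[, net$idx_endo, drop = FALSE] %*% w)
  surf + traj$traffic$phi * endo
}

#' Cross-inhibition between two gc cytokines
#'
#' Pretreat with one cytokine, then add a fixed dose of a second (both remain
#' present), and compare the second cytokine's signal with stimulation by the
#' second cytokine alone:
#' `inhibition = 100 * (1 - pSTAT_with_pretreat / pSTAT_alone)`, evaluated at
#' the end of the stimulation window.
#'
#' @param profile A `gc_profile`.
#' @param pre_ligand,fixed_ligand The two cytokines.
#' @param pre_doses Pre-treatment doses (nM).
#' @param fixed_dose Dose of the second cytokine (nM).
#' @param pre_min,stim_min Pretreatment and stimulation durations (min).
#' @param rates,traffic Model parameters (defaults used when omitted).
#' @return data.frame with `pre_dose_nM` and `percent_inhibition`.
#' @export
cross_inhibition <- function(profile, pre_ligand, pre_doses, fixed_ligand,
                             fixed_dose, pre_min = 10, stim_min = 10,
                             rates = default_rate_table(),
                             traffic = trafficking_params()) {
  net <- build_network(unique(c(pre_ligand, fixed_ligand)))
  syn <- .profile_synthesis(profile, traffic)
  y0 <- initial_state(profile, net, traffic)
  t_end <- pre_min + stim_min
  run <- function(events) {
    pr <- protocol(events, t_grid = c(0, t_end))
    tr <- simulate_protocol(y0, pr, net, rates, traffic, synthesis = syn)
    utils::tail(active_signal(tr, fixed_ligand), 1)
  }
  alone <- run(data.frame(ligand = fixed_ligand, concentration_nM = fixed_dose,
                          onset_min = pre_min))
  if (alone <= 0) stop("fixed-ligand response alone is zero; ",
                       "inhibition undefined")
  inhib <- vapply(pre_doses, function(d) {
    if (d == 0) return(0)
    both <- run(data.frame(
      ligand = c(pre_ligand, fixed_ligand),
      concentration_nM = c(d, fixed_dose), onset_min = c(0, pre_min)))
    100 * (1 - both / alone)
  }, numeric(1))
  data.frame(pre_dose_nM = pre_doses, percent_inhibition = inhib)
}

.profile_synthesis <- function(profile, traffic) {
  if (!is.null(profile$synthesis)) profile$synthesis
  else synthesis_from_surface(profile$surface, traffic)
}

#' Predicted pSTAT response grid over cells, ligand conditions and time
#'
#' Simulates every (cell, ligand, concentration) condition from its no-ligand
#' steady state and assembles a labeled 3-way response tensor
#' time x cell x condition, where a condition is a ligand-concentration pair
#' (labels `"<ligand>@<conc>nM"`).
#'
#' @param profiles List of `gc_profile`s.
#' @param ligands Ligands to stimulate with.
#' @param concentrations Doses (nM): numeric vector shared by all ligands, or
#'   a named list per ligand.
#' @param times Output times (min), starting at 0.
#' @param rates,traffic Model parameters.
#' @param scale pSTAT scale factor.
#' @return A 3-way array of class `response_tensor` with dimnames
#'   `time`, `cell`, `condition` and a `conditions` attribute table.
#' @export
dose_response_grid <- function(profiles, ligands, concentrations, times,
                               rates = default_rate_table(),
                               traffic = trafficking_params(), scale = 1) {
  if (length(profiles) == 0 || length(ligands) == 0 || length(times) == 0)
    stop("profiles, ligands and times must be non-empty")
  if (!is.list(concentrations))
    concentrations <- stats::setNames(
      rep(list(concentrations), length(ligands)), ligands)
  net <- build_network(ligands)
  conds <- do.call(rbind, lapply(ligands, function(lg)
    data.frame(ligand = lg, concentration_nM = concentrations[[lg]])))
  conds$label <- sprintf("%s@%gnM", conds$ligand, conds$concentration_nM)
  cellnames <- vapply(profiles, function(p) p$name, character(1))
  tensor <- array(0, dim = c(length(times), length(profiles), nrow(conds)),
                  dimnames = list(time = as.character(times),
                                  cell = cellnames, condition = conds$label))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    syn <- if (trafficking_off(traffic)) numeric(0)
           else .profile_synthesis(pr, traffic)
    y0 <- initial_state(pr, net, traffic)
    for (j in seq_len(nrow(conds))) {
      sd_ <- single_dose(conds$ligand[j], conds$concentration_nM[j],
                         t_grid = sort(unique(c(0, times))))
      tr <- simulate_protocol(y0, sd_, net, rates, traffic, synthesis = syn)
      sig <- pstat(active_signal(tr, conds$ligand[j]), scale)
      tensor[, i, j] <- sig[match(times, tr$times)]
    }
  }
  structure(tensor, conditions = conds, class = c("response_tensor", "array"))
}
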