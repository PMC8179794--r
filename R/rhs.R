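# ODE right-hand side: mass-action binding in two compartments plus
# first-order trafficking. For each surface species E with endosomal
# (area-normalized) counterpart I:
#   dE/dt = -E*k + k_rec*(1-f)*I*phi
#   dI/dt =  E*k/phi - k_rec*(1-f)*I - k_deg*f*I
# with k = k_endo (inactive) or k_endo_active (active), and f = f_sort for
# inactive species, 1 for active species. Receptor synthesis feeds the
# surface free-receptor pools at a constant rate. Endosomal free ligand
# gains from endosomal dissociation, is consumed by endosomal rebinding, and
# degrades at k_deg (lysosomal sorting fraction 1). Extracellular ligand is
# clamped (derivative exactly zero).
#
# The inner kernel is compiled (src/gc_rhs.cpp); make_rhs() precomputes the
# index vectors and effective rates once per (network, rates, traffic).

make_rhs <- function(network, rates, traffic, synthesis = numeric(0)) {
  stopifnot(inherits(network, "gc_network"), inherits(rates, "gc_rates"),
            inherits(traffic, "gc_traffic"))
  rx <- network$reactions
  n_sp <- network$n_species

  krev_s <- unname(rates$rev[rx$key])
  if (anyNA(krev_s)) stop("rate table missing key(s): ",
                          paste(rx$key[is.na(rates$rev[rx$key])], collapse = ", "))
  krev_e <- unname(endosomal_reverse(rates)[rx$key])

  ib <- which(rx$type == "bind")
  id <- which(rx$type == "dimer")

  act <- network$active
  k_in <- ifelse(act, traffic$k_endo_active, traffic$k_endo)
  f_i <- ifelse(act, 1, traffic$f_sort)
  rec_rate <- traffic$k_rec * (1 - f_i)
  endo_loss <- rec_rate + traffic$k_deg * f_i

  syn <- numeric(n_sp)
  if (length(synthesis) > 0) {
    unknown <- setdiff(names(synthesis), GC_RECEPTORS)
    if (length(unknown) > 0)
      stop("synthesis names not receptors: ", paste(unknown, collapse = ", "))
    synthesis <- synthesis[names(synthesis) %in% network$receptors]
    syn[match(names(synthesis), network$species$label)] <- synthesis
  }

  P <- list(
    n_sp = n_sp,
    bind_rec = rx$i_lhs[ib] - 1L,
    bind_prod = rx$i_prod[ib] - 1L,
    bind_xlig = unname(network$idx_xlig[rx$ligand[ib]]) - 1L,
    bind_elig = unname(network$idx_elig[rx$ligand[ib]]) - 1L,
    dim_a = rx$i_lhs[id] - 1L,
    dim_b = rx$i_partner[id] - 1L,
    dim_p = rx$i_prod[id] - 1L,
    krevs_b = krev_s[ib], kreve_b = krev_e[ib],
    krevs_d = krev_s[id], kreve_d = krev_e[id],
    k_in = k_in, rec_rate = rec_rate, endo_loss = endo_loss, syn = syn,
    kbnd = rates$k_bnd, kfwd = rates$k_fwd, phi = traffic$phi,
    c2n = count_to_nM(1, traffic$v_endo_fL), kdeg = traffic$k_deg,
    elig_idx = unname(network$idx_elig) - 1L)

  deriv <- function(y) gc_deriv_cpp(y, P)
  list(deriv = deriv, P = P, network = network, rates = rates,
       traffic = traffic, synthesis = synthesis)
}

#' Time derivative of the system state
#'
#' Evaluates the model's full right-hand side: mass-action binding and
#' unbinding in the surface and endosomal compartments (endosomal reverse
#' rates carry the acidic-pH penalty), first-order trafficking between
#' compartments, constant receptor synthesis, and the endosomal free-ligand
#' mass balance. Extracellular ligand is clamped (derivative zero).
#'
#' @param state Named non-negative state vector laid out as in
#'   [empty_state()].
#' @param network A `gc_network`.
#' @param rates A `gc_rates` table.
#' @param traffic A `gc_traffic` parameter set.
#' @param synthesis Named per-receptor synthesis rates (#/cell/min);
#'   receptors omitted default to zero.
#' @return Named numeric derivative vector (same layout as `state`).
#' @export
network_rhs <- function(state, network, rates, traffic,
                        synthesis = numeric(0)) {
  if (length(state) != network$n_state)
    stop("state has length ", length(state), ", expected ", network$n_state)
  if (any(state < 0)) stop("state entries must be non-negative")
  ev <- make_rhs(network, rates, traffic, synthesis)
  stats::setNames(ev$deriv(unname(state)), network$state_names)
}

# .Call wrappers for the compiled kernel (registered in src/init.cpp)
gc_set_model <- function(P) invisible(.Call(`_gckin_gc_set_model`, P))
gc_deriv_cpp <- function(y, P) .Call(`_gckin_gc_deriv_cpp`, y, P)
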