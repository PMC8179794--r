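# Species and reaction enumeration for the common gamma-chain (gc) cytokine
# family. IL-2 and IL-15 each bind a signaling-deficient alpha chain
# (IL-2Ra / IL-15Ra) and the shared signaling-competent IL-2Rb; IL-4, IL-7,
# IL-9 and IL-21 each bind a single signaling-competent private receptor.
# Every ligand-receptor complex may then dimerize with the shared gc chain.
# Complexes carrying two signaling-competent chains are "active" (drive STAT
# phosphorylation).

GC_LIGANDS <- c("IL-2", "IL-15", "IL-4", "IL-7", "IL-9", "IL-21")

# per-ligand receptor slots: alpha = signaling-deficient chain (or NA),
# private = signaling-competent private chain
GC_SLOTS <- list(
  "IL-2"  = list(alpha = "IL-2Ra",  private = "IL-2Rb"),
  "IL-15" = list(alpha = "IL-15Ra", private = "IL-2Rb"),
  "IL-4"  = list(alpha = NA,        private = "IL-4Ra"),
  "IL-7"  = list(alpha = NA,        private = "IL-7Ra"),
  "IL-9"  = list(alpha = NA,        private = "IL-9R"),
  "IL-21" = list(alpha = NA,        private = "IL-21Ra")
)

# reverse-rate key assignment per ligand, following the conventional numbering
# (IL-2: k1..k12, IL-15: k13..k24, IL-7: k25/k27, IL-4: k32/k33). IL-9 and
# IL-21 carry no printed indices; slots k28/k29 and k30/k31 are assigned here.
GC_RATEKEYS <- list(
  "IL-2" = c(bind_alpha = "k_1_rev", bind_beta = "k_2_rev",
             gc_on_alpha = "k_4_rev", gc_on_beta = "k_5_rev",
             alpha_off_full = "k_8_rev", beta_off_full = "k_9_rev",
             gc_off_full = "k_10_rev", beta_off_ab = "k_11_rev",
             alpha_off_ab = "k_12_rev"),
  "IL-15" = c(bind_alpha = "k_13_rev", bind_beta = "k_14_rev",
              gc_on_alpha = "k_16_rev", gc_on_beta = "k_17_rev",
              alpha_off_full = "k_20_rev", beta_off_full = "k_21_rev",
              gc_off_full = "k_22_rev", beta_off_ab = "k_23_rev",
              alpha_off_ab = "k_24_rev"),
  "IL-7"  = c(bind_private = "k_25_rev", gc_dim = "k_27_rev"),
  "IL-4"  = c(bind_private = "k_32_rev", gc_dim = "k_33_rev"),
  "IL-9"  = c(bind_private = "k_28_rev", gc_dim = "k_29_rev"),
  "IL-21" = c(bind_private = "k_30_rev", gc_dim = "k_31_rev")
)

species_label <- function(ligand, chains) paste0(ligand, ":", paste(chains, collapse = "."))

#' Enumerate species and reactions for a subset of the gc cytokine family
#'
#' Builds the full state-space layout for a deterministic mass-action model of
#' the selected ligands: free receptors and ligand-receptor complexes in the
#' surface and endosomal compartments, endosomal free-ligand concentrations,
#' and clamped extracellular ligand concentrations. Shared chains (IL-2Rb for
#' IL-2/IL-15, gc for all ligands) appear once per compartment.
#'
#' For ligands with an alpha slot (IL-2, IL-15) the complex set is
#' \{L.a, L.b, L.a.b, L.a.gc, L.b.gc, L.a.b.gc\}; for single-private-receptor
#' ligands it is \{L.R, L.R.gc\}. Active species (two signaling-competent
#' chains) are \{L.b.gc, L.a.b.gc\} and \{L.R.gc\} respectively.
#'
#' @param ligands Character vector, a non-empty subset of
#'   IL-2, IL-15, IL-4, IL-7, IL-9, IL-21.
#' @return An object of class `gc_network`: species tables, reaction list,
#'   state-vector index maps and stoichiometry matrices.
#' @examples
#' net <- build_network("IL-2")
#' nrow(net$species)   # 9 receptor species per compartment
#' @export
build_network <- function(ligands) {
  if (length(ligands) == 0) stop("at least one ligand is required")
  bad <- setdiff(ligands, GC_LIGANDS)
  if (length(bad) > 0)
    stop("unknown ligand identifier(s): ", paste(bad, collapse = ", "))
  ligands <- GC_LIGANDS[GC_LIGANDS %in% ligands]  # canonical order
  cache_key <- paste(ligands, collapse = "|")
  cached <- .gc_net_cache[[cache_key]]
  if (!is.null(cached)) return(cached)

  receptors <- character(0)
  for (lg in ligands) {
    sl <- GC_SLOTS[[lg]]
    if (!is.na(sl$alpha)) receptors <- c(receptors, sl$alpha)
    receptors <- c(receptors, sl$private)
  }
  receptors <- unique(c(receptors, "gc"))

  # receptor species table (per compartment): free receptors then complexes
  sp <- data.frame(label = receptors, ligand = NA_character_,
                   active = FALSE, stringsAsFactors = FALSE)
  sp$chains <- as.list(receptors)
  rxn <- list()
  for (lg in ligands) {
    sl <- GC_SLOTS[[lg]]
    keys <- GC_RATEKEYS[[lg]]
    if (!is.na(sl$alpha)) {
      a <- sl$alpha; b <- sl$private
      combos <- list(c(a), c(b), c(a, b), c(a, "gc"), c(b, "gc"), c(a, b, "gc"))
      for (ch in combos) {
        act <- all(c(b, "gc") %in% ch)  # two signaling-competent chains
        sp <- rbind(sp, data.frame(label = species_label(lg, ch), ligand = lg,
                                   active = act, chains = I(list(ch)),
                                   stringsAsFactors = FALSE))
      }
      L  <- function(ch) species_label(lg, ch)
      rxn <- c(rxn, list(
        list(type = "bind",  ligand = lg, lhs = a, product = L(a), key = keys[["bind_alpha"]]),
        list(type = "bind",  ligand = lg, lhs = b, product = L(b), key = keys[["bind_beta"]]),
        list(type = "dimer", ligand = lg, lhs = L(a), partner = b,
             product = L(c(a, b)), key = keys[["beta_off_ab"]]),
        list(type = "dimer", ligand = lg, lhs = L(b), partner = a,
             product = L(c(a, b)), key = keys[["alpha_off_ab"]]),
        list(type = "dimer", ligand = lg, lhs = L(a), partner = "gc",
             product = L(c(a, "gc")), key = keys[["gc_on_alpha"]]),
        list(type = "dimer", ligand = lg, lhs = L(b), partner = "gc",
             product = L(c(b, "gc")), key = keys[["gc_on_beta"]]),
        list(type = "dimer", ligand = lg, lhs = L(c(a, b)), partner = "gc",
             product = L(c(a, b, "gc")), key = keys[["gc_off_full"]]),
        list(type = "dimer", ligand = lg, lhs = L(c(b, "gc")), partner = a,
             product = L(c(a, b, "gc")), key = keys[["alpha_off_full"]]),
        list(type = "dimer", ligand = lg, lhs = L(c(a, "gc")), partner = b,
             product = L(c(a, b, "gc")), key = keys[["beta_off_full"]])
      ))
    } else {
      r <- sl$private
      L <- function(ch) species_label(lg, ch)
      sp <- rbind(sp,
        data.frame(label = L(r), ligand = lg, active = FALSE,
                   chains = I(list(r)), stringsAsFactors = FALSE),
        data.frame(label = L(c(r, "gc")), ligand = lg, active = TRUE,
                   chains = I(list(c(r, "gc"))), stringsAsFactors = FALSE))
      rxn <- c(rxn, list(
        list(type = "bind",  ligand = lg, lhs = r, product = L(r),
             key = keys[["bind_private"]]),
        list(type = "dimer", ligand = lg, lhs = L(r), partner = "gc",
             product = L(c(r, "gc")), key = keys[["gc_dim"]])
      ))
    }
  }

  n_sp <- nrow(sp)
  state_names <- c(paste0("surf/", sp$label), paste0("endo/", sp$label),
                   paste0("endo/lig:", ligands), paste0("ext/lig:", ligands))
  idx_surf <- seq_len(n_sp)
  idx_endo <- n_sp + seq_len(n_sp)
  idx_elig <- stats::setNames(2L * n_sp + seq_along(ligands), ligands)
  idx_xlig <- stats::setNames(2L * n_sp + length(ligands) + seq_along(ligands),
                              ligands)

  spi <- stats::setNames(seq_len(n_sp), sp$label)
  rxdf <- do.call(rbind, lapply(rxn, function(r) data.frame(
    type = r$type, ligand = r$ligand, lhs = r$lhs,
    partner = if (r$type == "dimer") r$partner else NA_character_,
    product = r$product, key = r$key, stringsAsFactors = FALSE)))
  rxdf$i_lhs <- spi[rxdf$lhs]
  rxdf$i_partner <- ifelse(is.na(rxdf$partner), NA_integer_, spi[rxdf$partner])
  rxdf$i_prod <- spi[rxdf$product]

  # per-compartment stoichiometry over reaction net fluxes (receptor species
  # rows only; ligand bookkeeping handled in the RHS)
  S <- matrix(0, n_sp, nrow(rxdf))
  for (j in seq_len(nrow(rxdf))) {
    S[rxdf$i_lhs[j], j] <- S[rxdf$i_lhs[j], j] - 1
    if (!is.na(rxdf$i_partner[j]))
      S[rxdf$i_partner[j], j] <- S[rxdf$i_partner[j], j] - 1
    S[rxdf$i_prod[j], j] <- S[rxdf$i_prod[j], j] + 1
  }

  # chain membership matrix (chains x species), for conservation accounting
  chains <- receptors
  C <- matrix(0, length(chains), n_sp, dimnames = list(chains, sp$label))
  for (i in seq_len(n_sp)) C[sp$chains[[i]], i] <- 1

  net <- structure(list(
    ligands = ligands, receptors = receptors, species = sp,
    reactions = rxdf, stoich = S, chain_matrix = C,
    state_names = state_names, n_state = length(state_names),
    n_species = n_sp, idx_surf = idx_surf, idx_endo = idx_endo,
    idx_elig = idx_elig, idx_xlig = idx_xlig,
    active = sp$active,
    active_by_ligand = lapply(stats::setNames(ligands, ligands), function(lg)
      which(sp$active & !is.na(sp$ligand) & sp$ligand == lg))
  ), class = "gc_network")
  .gc_net_cache[[cache_key]] <- net
  net
}

# memoized networks (construction is pure; topology depends only on ligands)
.gc_net_cache <- new.env(parent = emptyenv())

#' @exportS3Method print gc_network
print.gc_network <- function(x, ...) {
  cat("gc cytokine network:", paste(x$ligands, collapse = ", "), "\n")
  cat(sprintf("  %d receptor species per compartment (%d receptors, %d complexes)\n",
              x$n_species, length(x$receptors), x$n_species - length(x$receptors)))
  cat(sprintf("  %d state variables (%d clamped extracellular ligands)\n",
              x$n_state, length(x$ligands)))
  invisible(x)
}

#' Labels of active (signaling) species
#'
#' Active complexes contain two signaling-competent chains: for IL-2/IL-15
#' these are L.IL-2Rb.gc and L.a.IL-2Rb.gc; for IL-4/7/9/21 the single
#' L.R.gc complex.
#'
#' @param network A `gc_network`.
#' @param ligand Optional ligand to restrict to.
#' @return Character vector of species labels.
#' @export
active_species <- function(network, ligand = NULL) {
  sp <- network$species
  keep <- sp$active
  if (!is.null(ligand)) keep <- keep & !is.na(sp$ligand) & sp$ligand == ligand
  sp$label[keep]
}

#' Zero system state for a network
#'
#' @param network A `gc_network`.
#' @return Named numeric vector of zeros, one entry per state variable.
#' @export
empty_state <- function(network) {
  stats::setNames(numeric(network$n_state), network$state_names)
}
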