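# Independent oracles, coded straight from the model's printed structure and
# kept deliberately separate from the package internals.

# ---- hand-coded IL-2 right-hand side (both compartments + trafficking) ----
# State: named vector in the package layout for build_network("IL-2").
# Rates passed explicitly; endosomal reverse rates are surface x penalty.
oracle_il2_rhs <- function(y, kbnd, kfwd, kr, pen, traffic, synthesis) {
  # kr: named k_1_rev ... k_12_rev
  g <- function(nm) unname(y[[nm]])
  c2n <- 1 / (0.602214076 * traffic$v_endo_fL)
  phi <- traffic$phi
  binding <- function(pre, L, fac) {
    a <- g(paste0(pre, "IL-2Ra")); b <- g(paste0(pre, "IL-2Rb"))
    gc <- g(paste0(pre, "gc"))
    La <- g(paste0(pre, "IL-2:IL-2Ra")); Lb <- g(paste0(pre, "IL-2:IL-2Rb"))
    Lab <- g(paste0(pre, "IL-2:IL-2Ra.IL-2Rb"))
    Lag <- g(paste0(pre, "IL-2:IL-2Ra.gc")); Lbg <- g(paste0(pre, "IL-2:IL-2Rb.gc"))
    Labg <- g(paste0(pre, "IL-2:IL-2Ra.IL-2Rb.gc"))
    k1 <- kr[["k_1_rev"]] * fac; k2 <- kr[["k_2_rev"]] * fac
    k4 <- kr[["k_4_rev"]] * fac; k5 <- kr[["k_5_rev"]] * fac
    k8 <- kr[["k_8_rev"]] * fac; k9 <- kr[["k_9_rev"]] * fac
    k10 <- kr[["k_10_rev"]] * fac; k11 <- kr[["k_11_rev"]] * fac
    k12 <- kr[["k_12_rev"]] * fac
    d <- c(
      `IL-2Ra` = -kbnd * a * L + k1 * La + k8 * Labg -
        kfwd * (a * Lb + a * Lbg) + k12 * Lab,
      `IL-2Rb` = -kbnd * b * L + k2 * Lb + k9 * Labg -
        kfwd * (b * La + b * Lag) + k11 * Lab,
      gc = -kfwd * (Lb * gc + La * gc + Lab * gc) + k5 * Lbg + k4 * Lag +
        k10 * Labg,
      `IL-2:IL-2Ra` = -kfwd * (La * b + La * gc) + k11 * Lab + k4 * Lag +
        kbnd * L * a - k1 * La,
      `IL-2:IL-2Rb` = -kfwd * (Lb * a + Lb * gc) + k12 * Lab + k5 * Lbg +
        kbnd * L * b - k2 * Lb,
      `IL-2:IL-2Ra.IL-2Rb` = kfwd * (Lb * a + La * b - Lab * gc) +
        k10 * Labg - k11 * Lab - k12 * Lab,
      `IL-2:IL-2Ra.gc` = k9 * Labg + kfwd * (La * gc - Lag * b) - k4 * Lag,
      `IL-2:IL-2Rb.gc` = k8 * Labg + kfwd * (Lb * gc - Lbg * a) - k5 * Lbg,
      `IL-2:IL-2Ra.IL-2Rb.gc` = kfwd * (Lbg * a + Lag * b + Lab * gc) -
        (k8 + k9 + k10) * Labg)
    # net ligand-consuming flux (the two ligand-binding reactions only)
    lig_net <- (kbnd * a * L - k1 * La) + (kbnd * b * L - k2 * Lb)
    list(d = d, lig_net = lig_net)
  }
  s <- binding("surf/", y[["ext/lig:IL-2"]], 1)
  e <- binding("endo/", max(y[["endo/lig:IL-2"]], 0), pen)
  sp <- names(s$d)
  act <- sp %in% c("IL-2:IL-2Rb.gc", "IL-2:IL-2Ra.IL-2Rb.gc")
  k_in <- ifelse(act, traffic$k_endo_active, traffic$k_endo)
  f_i <- ifelse(act, 1, traffic$f_sort)
  ys <- y[paste0("surf/", sp)]; ye <- y[paste0("endo/", sp)]
  d <- y * 0
  d[paste0("surf/", sp)] <- s$d - k_in * ys +
    traffic$k_rec * (1 - f_i) * ye * phi
  d[paste0("surf/", sp)][1:3] <- d[paste0("surf/", sp)][1:3] +
    synthesis[c("IL-2Ra", "IL-2Rb", "gc")]
  d[paste0("endo/", sp)] <- e$d + k_in * ys / phi -
    traffic$k_rec * (1 - f_i) * ye - traffic$k_deg * f_i * ye
  d[["endo/lig:IL-2"]] <- -phi * c2n * e$lig_net -
    traffic$k_deg * max(y[["endo/lig:IL-2"]], 0)
  d[["ext/lig:IL-2"]] <- 0
  d
}

# ---- brute-force detailed-balance check over all binding cycles ----------
# Builds the complex graph per ligand by hand (edges labeled with their
# equilibrium constants), computes each node's formation constant along a
# BFS spanning tree, and checks every non-tree edge for consistency --
# equivalent to all cycle products equalling one.
oracle_cycle_check <- function(rates, tol = 1e-9) {
  edges_for <- function(keys) {
    # from, to, Keq (kf / krev); node "L" is free ligand
    rbind(
      data.frame(from = "L",   to = "La",   kf = rates$k_bnd, kr = keys["bind_alpha"]),
      data.frame(from = "L",   to = "Lb",   kf = rates$k_bnd, kr = keys["bind_beta"]),
      data.frame(from = "La",  to = "Lab",  kf = rates$k_fwd, kr = keys["beta_off_ab"]),
      data.frame(from = "Lb",  to = "Lab",  kf = rates$k_fwd, kr = keys["alpha_off_ab"]),
      data.frame(from = "La",  to = "Lag",  kf = rates$k_fwd, kr = keys["gc_on_alpha"]),
      data.frame(from = "Lb",  to = "Lbg",  kf = rates$k_fwd, kr = keys["gc_on_beta"]),
      data.frame(from = "Lab", to = "Labg", kf = rates$k_fwd, kr = keys["gc_off_full"]),
      data.frame(from = "Lbg", to = "Labg", kf = rates$k_fwd, kr = keys["alpha_off_full"]),
      data.frame(from = "Lag", to = "Labg", kf = rates$k_fwd, kr = keys["beta_off_full"]))
  }
  keysets <- list(
    c(bind_alpha = "k_1_rev", bind_beta = "k_2_rev", gc_on_alpha = "k_4_rev",
      gc_on_beta = "k_5_rev", alpha_off_full = "k_8_rev",
      beta_off_full = "k_9_rev", gc_off_full = "k_10_rev",
      beta_off_ab = "k_11_rev", alpha_off_ab = "k_12_rev"),
    c(bind_alpha = "k_13_rev", bind_beta = "k_14_rev",
      gc_on_alpha = "k_16_rev", gc_on_beta = "k_17_rev",
      alpha_off_full = "k_20_rev", beta_off_full = "k_21_rev",
      gc_off_full = "k_22_rev", beta_off_ab = "k_23_rev",
      alpha_off_ab = "k_24_rev"))
  worst <- 0
  for (keys in keysets) {
    ed <- edges_for(keys)
    ed$keq <- ed$kf / rates$rev[ed$kr]
    Kform <- c(L = 1)
    frontier <- "L"
    tree <- rep(FALSE, nrow(ed))
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (i in seq_len(nrow(ed))) {
        if (!tree[i] && ed$from[i] %in% names(Kform) &&
            !(ed$to[i] %in% names(Kform))) {
          Kform[ed$to[i]] <- Kform[[ed$from[i]]] * ed$keq[i]
          tree[i] <- TRUE
          nxt <- c(nxt, ed$to[i])
        }
      }
      frontier <- nxt
    }
    # every edge (tree or not) must be consistent with the formation constants
    for (i in seq_len(nrow(ed))) {
      ratio <- Kform[[ed$to[i]]] / (Kform[[ed$from[i]]] * ed$keq[i])
      worst <- max(worst, abs(ratio - 1))
    }
  }
  worst
}

# ---- algebraic binding equilibrium for the IL-2 system (no trafficking) --
# Clamped ligand L (nM), receptor totals (at, bt, gt); damped fixed-point on
# the free receptors. Returns named species abundances.
oracle_il2_equilibrium <- function(L, at, bt, gt, rates,
                                   tol = 1e-12, max_iter = 20000) {
  kb <- rates$k_bnd; kf <- rates$k_fwd; kr <- rates$rev
  cLa <- kb / kr[["k_1_rev"]] * L
  cLb <- kb / kr[["k_2_rev"]] * L
  cLab <- cLa * kf / kr[["k_11_rev"]]
  cLag <- cLa * kf / kr[["k_4_rev"]]
  cLbg <- cLb * kf / kr[["k_5_rev"]]
  cLabg <- cLab * kf / kr[["k_10_rev"]]
  a <- at; b <- bt; g <- gt
  for (it in seq_len(max_iter)) {
    a2 <- at / (1 + cLa + cLab * b + cLag * g + cLabg * b * g)
    b2 <- bt / (1 + cLb + cLab * a + cLbg * g + cLabg * a * g)
    g2 <- gt / (1 + cLag * a + cLbg * b + cLabg * a * b)
    del <- max(abs(a2 - a), abs(b2 - b), abs(g2 - g))
    a <- 0.5 * a + 0.5 * a2; b <- 0.5 * b + 0.5 * b2; g <- 0.5 * g + 0.5 * g2
    if (del < tol * max(at, bt, gt)) break
  }
  c(`IL-2Ra` = a, `IL-2Rb` = b, gc = g,
    `IL-2:IL-2Ra` = cLa * a, `IL-2:IL-2Rb` = cLb * b,
    `IL-2:IL-2Ra.IL-2Rb` = cLab * a * b,
    `IL-2:IL-2Ra.gc` = cLag * a * g, `IL-2:IL-2Rb.gc` = cLbg * b * g,
    `IL-2:IL-2Ra.IL-2Rb.gc` = cLabg * a * b * g)
}

# default objects shared across tests
gc_default_rates <- default_rate_table()
gc_default_traffic <- trafficking_params()
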