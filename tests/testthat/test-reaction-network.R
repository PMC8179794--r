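# Species enumeration, rate tables, detailed balance and the ODE
# right-hand side.

test_that("species enumeration matches the family topology", {
  net2 <- build_network("IL-2")
  expect_equal(nrow(net2$species), 9)  # 3 free receptors + 6 complexes
  expect_setequal(net2$receptors, c("IL-2Ra", "IL-2Rb", "gc"))

  net4 <- build_network("IL-4")
  expect_equal(nrow(net4$species), 4)  # 2 free receptors + 2 complexes
  expect_setequal(net4$receptors, c("IL-4Ra", "gc"))

  full <- build_network(c("IL-2", "IL-15", "IL-4", "IL-7", "IL-9", "IL-21"))
  expect_equal(length(full$receptors), 8)
  expect_equal(full$n_species, 28)          # 8 receptors + 20 complexes
  expect_equal(full$n_state, 68)            # 2x28 + 6 endo + 6 clamped lig
  # dynamic states exclude the clamped extracellular ligands
  expect_equal(full$n_state - length(full$ligands), 62)

  expect_error(build_network(character(0)), "at least one")
  expect_error(build_network(c("IL-2", "IL-99")), "IL-99")
})

test_that("species index is a bijection and active sets are correct", {
  full <- build_network(GC_LIGANDS)
  expect_false(anyDuplicated(full$state_names) > 0)
  expect_setequal(active_species(full, "IL-2"),
                  c("IL-2:IL-2Rb.gc", "IL-2:IL-2Ra.IL-2Rb.gc"))
  expect_setequal(active_species(full, "IL-15"),
                  c("IL-15:IL-2Rb.gc", "IL-15:IL-15Ra.IL-2Rb.gc"))
  expect_setequal(active_species(full, "IL-4"), "IL-4:IL-4Ra.gc")
  expect_setequal(active_species(full, "IL-7"), "IL-7:IL-7Ra.gc")
})

test_that("default rate table reproduces the literature constants", {
  r <- gc_default_rates
  expect_equal(r$k_bnd, 0.6)                      # 1e7 M^-1 s^-1 in nM/min
  expect_equal(unname(r$rev["k_5_rev"]), 1.5)
  expect_equal(unname(r$rev["k_10_rev"]), 12)
  expect_equal(unname(r$rev["k_11_rev"]), 63)
  # binary reverse rates are KD x k_bnd
  expect_equal(unname(r$rev["k_1_rev"]), 10 * 0.6)
  expect_equal(unname(r$rev["k_2_rev"]), 144 * 0.6)
  expect_equal(unname(r$rev["k_13_rev"]), 0.065 * 0.6)
  expect_equal(unname(r$rev["k_14_rev"]), 438 * 0.6)
  expect_equal(unname(r$rev["k_25_rev"]), 59 * 0.6)   # 35.4
  expect_equal(unname(r$rev["k_32_rev"]), 1.0 * 0.6)
  expect_equal(unname(r$rev["k_28_rev"]), 0.1 * 0.6)
  expect_equal(unname(r$rev["k_30_rev"]), 0.07 * 0.6)
  expect_equal(r$endosomal_penalty, 5)
  expect_true(all(r$rev > 0))
})

test_that("detailed balance derives the dependent rates and closes cycles", {
  r <- gc_default_rates
  expect_equal(unname(r$rev["k_12_rev"]), 4.375)       # 6*63/86.4
  expect_equal(unname(r$rev["k_8_rev"]), 35.0)         # 12*4.375/1.5
  expect_equal(unname(r$rev["k_9_rev"]),
               unname(r$rev["k_10_rev"] * r$rev["k_11_rev"] / r$rev["k_4_rev"]))
  expect_lt(oracle_cycle_check(r), 1e-9)

  # idempotence: a balanced table is returned unchanged
  r2 <- enforce_detailed_balance(r)
  expect_equal(r2$rev, r$rev)

  # rejection names the offending rate
  bad <- r; bad$rev[["k_5_rev"]] <- -1
  expect_error(enforce_detailed_balance(bad), "k_5_rev")

  # perturbing an independent rate still yields closed cycles
  r3 <- r; r3$rev[["k_4_rev"]] <- 17; r3 <- enforce_detailed_balance(r3)
  expect_lt(oracle_cycle_check(r3), 1e-9)
})

test_that("rhs matches hand-evaluations of the printed equations", {
  net <- build_network("IL-2")
  r <- gc_default_rates
  r$k_fwd <- 0.01
  tr <- no_trafficking()
  y <- empty_state(net)
  y["surf/gc"] <- 100
  y["surf/IL-2:IL-2Rb"] <- 50
  y["surf/IL-2:IL-2Rb.gc"] <- 20
  d <- network_rhs(y, net, r, tr)
  # d gc/dt = -kfwd*[Lb]*gc + k5*[Lbg] = -0.01*50*100 + 1.5*20
  expect_equal(unname(d["surf/gc"]), -20)

  # trafficking-only hand example on a free inactive receptor
  tr2 <- trafficking_params(k_endo = 0.08, k_endo_active = 0.8,
                            f_sort = 1 / 3, k_rec = 0.1, k_deg = 0.03)
  y2 <- empty_state(net)
  y2["surf/IL-2Ra"] <- 1000; y2["endo/IL-2Ra"] <- 300
  d2 <- network_rhs(y2, net, gc_default_rates, tr2)
  expect_equal(unname(d2["surf/IL-2Ra"]), -80 + 0.1 * (2 / 3) * 300 * 0.5) # -70
  expect_equal(unname(d2["endo/IL-2Ra"]), 160 - 20 - 3)                    # 137

  expect_error(network_rhs(y - 1, net, r, tr2), "non-negative")
  expect_error(network_rhs(y[-1], net, r, tr2), "length")
})

test_that("rhs equals the independently coded reaction-list oracle", {
  net <- build_network("IL-2")
  r <- gc_default_rates
  tr <- gc_default_traffic
  syn <- c("IL-2Ra" = 1.3, "IL-2Rb" = 0.7, "gc" = 2.1)
  set.seed(42)
  for (i in 1:100) {
    y <- empty_state(net)
    y[] <- stats::runif(net$n_state, 0, 1000)
    y["ext/lig:IL-2"] <- stats::runif(1, 0, 10)
    y["endo/lig:IL-2"] <- stats::runif(1, 0, 2)
    d_pkg <- network_rhs(y, net, r, tr, synthesis = syn)
    d_or <- oracle_il2_rhs(y, r$k_bnd, r$k_fwd, r$rev, r$endosomal_penalty,
                           tr, syn)
    expect_equal(unname(d_pkg), unname(d_or[names(d_pkg)]),
                 tolerance = 1e-10)
  }
})

test_that("rhs is structurally positive at the boundary", {
  net <- build_network(c("IL-2", "IL-7"))
  r <- gc_default_rates
  tr <- gc_default_traffic
  set.seed(7)
  for (i in 1:25) {
    y <- empty_state(net)
    y[] <- stats::runif(net$n_state, 0, 500)
    zero <- sample(net$n_state, 10)
    y[zero] <- 0
    d <- network_rhs(y, net, r, tr)
    expect_true(all(d[zero] >= -1e-12))
  }
})

test_that("per-chain mass is conserved without synthesis and degradation", {
  net <- build_network("IL-2")
  r <- gc_default_rates
  tr <- trafficking_params(k_endo = 0.02, k_endo_active = 0.2, f_sort = 1 / 3,
                           k_rec = 0.1, k_deg = 1e-12)
  tr$k_deg <- 0
  y0 <- empty_state(net)
  y0["surf/IL-2Ra"] <- 2000; y0["surf/IL-2Rb"] <- 800; y0["surf/gc"] <- 2500
  y0["endo/IL-2Ra"] <- 300; y0["endo/IL-2Rb"] <- 100; y0["endo/gc"] <- 400
  trj <- simulate_protocol(y0, single_dose("IL-2", 1, seq(0, 1000, by = 100)),
                           net, r, tr)
  for (chain in c("IL-2Ra", "IL-2Rb", "gc")) {
    tot <- chain_total(trj, chain)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
})

test_that("equilibrium is independent of assembly order", {
  # trafficking off: same chain totals reached from different pre-bound
  # initial conditions converge to the same binding equilibrium
  net <- build_network("IL-2")
  r <- gc_default_rates
  tr <- no_trafficking()
  at <- 1500; bt <- 900; gt <- 1200
  y1 <- empty_state(net)
  y1["surf/IL-2Ra"] <- at; y1["surf/IL-2Rb"] <- bt; y1["surf/gc"] <- gt
  y2 <- empty_state(net)
  y2["surf/IL-2Ra"] <- at - 400; y2["surf/IL-2Rb"] <- bt - 400
  y2["surf/gc"] <- gt - 400
  y2["surf/IL-2:IL-2Ra.IL-2Rb.gc"] <- 400
  prot <- single_dose("IL-2", 0.5, c(0, 5000))
  s1 <- simulate_protocol(y1, prot, net, r, tr)$states[2, ]
  s2 <- simulate_protocol(y2, prot, net, r, tr)$states[2, ]
  ii <- net$idx_surf
  expect_equal(unname(s1[ii]), unname(s2[ii]), tolerance = 1e-6)
})

test_that("endosomal concentration conversions are exact inverses", {
  expect_equal(count_to_nM(0), 0)
  expect_equal(count_to_nM(1), 1 / (0.602214076 * 10))   # ~0.166 nM
  expect_equal(count_to_nM(6.02214076), 1.0)
  expect_equal(nM_to_count(count_to_nM(123.4)), 123.4)
  expect_error(count_to_nM(-1), "non-negative")
  expect_error(nM_to_count(-1), "non-negative")
})

test_that("rate/trafficking config round-trips through YAML", {
  r <- gc_default_rates
  r$endo_rev <- r$rev * 1.2
  tr <- gc_default_traffic
  f <- tempfile(fileext = ".yaml")
  write_config(r, tr, f)
  back <- read_config(f)
  expect_equal(back$rates$rev[order(names(back$rates$rev))],
               r$rev[order(names(r$rev))], tolerance = 1e-12)
  expect_equal(back$rates$k_fwd, r$k_fwd)
  expect_equal(back$traffic$f_sort, tr$f_sort)
  unlink(f)
})
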