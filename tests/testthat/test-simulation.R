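# Steady state, protocol integration and readouts.

test_that("no-ligand steady state matches the trafficking closed form", {
  net <- build_network("IL-2")
  tr <- trafficking_params(k_endo = 0.08, k_endo_active = 0.8, f_sort = 1 / 3,
                           k_rec = 0.1, k_deg = 0.01)
  pr <- cell_profile("x", synthesis = c("IL-2Rb" = 1))
  y <- steady_state(pr, net, tr)
  expect_equal(unname(y["surf/IL-2Rb"]), 262.5)
  expect_equal(unname(y["endo/IL-2Rb"]), 600)

  # the returned state is a fixed point of the full rhs
  d <- network_rhs(y, net, gc_default_rates, tr,
                   synthesis = pr$synthesis)
  expect_lt(max(abs(d)), 1e-9 * max(y))

  # zero synthesis gives the zero state
  y0 <- steady_state(cell_profile("z", synthesis = c("IL-2Rb" = 0)), net, tr)
  expect_true(all(y0 == 0))
})

test_that("long-time integration reproduces the algebraic steady state", {
  net <- build_network("IL-2")
  tr <- gc_default_traffic
  pr <- cell_profile("x", synthesis = c("IL-2Ra" = 1.2, "IL-2Rb" = 0.6,
                                        "gc" = 2))
  target <- steady_state(pr, net, tr)
  trj <- simulate_protocol(empty_state(net),
                           single_dose("IL-2", 0, c(0, 10000)),
                           net, gc_default_rates, tr,
                           synthesis = pr$synthesis)
  final <- trj$states[nrow(trj$states), ]
  nz <- which(target > 0)
  expect_equal(unname(final[nz]), unname(target[nz]), tolerance = 1e-3)
})

test_that("synthesis_from_surface inverts the steady-state closed form", {
  tr <- trafficking_params(k_endo = 0.08, k_endo_active = 0.8, f_sort = 1 / 3,
                           k_rec = 0.1, k_deg = 0.01)
  expect_equal(unname(synthesis_from_surface(c("IL-2Rb" = 262.5), tr)), 1.0)
  expect_equal(unname(synthesis_from_surface(c("IL-2Rb" = 0), tr)), 0)
  expect_error(synthesis_from_surface(c("IL-2Rb" = -5), tr), "non-negative")

  net <- build_network("IL-2")
  set.seed(11)
  for (i in 1:100) {
    tri <- trafficking_params(k_endo = stats::runif(1, 0.005, 0.2),
                              k_endo_active = stats::runif(1, 0.05, 1),
                              f_sort = stats::runif(1, 0.1, 0.9),
                              k_rec = stats::runif(1, 0.01, 0.3),
                              k_deg = stats::runif(1, 0.005, 0.1))
    surf <- c("IL-2Ra" = stats::runif(1, 10, 5000),
              "IL-2Rb" = stats::runif(1, 10, 5000),
              "gc" = stats::runif(1, 10, 5000))
    v <- synthesis_from_surface(surf, tri)
    y <- steady_state(cell_profile("p", synthesis = v), net, tri)
    expect_equal(unname(y[paste0("surf/", names(surf))]), unname(surf),
                 tolerance = 1e-8)
  }
})

test_that("zero-dose protocols hold the steady state constant", {
  net <- build_network("IL-2")
  pr <- cell_profile("x", synthesis = c("IL-2Ra" = 1, "IL-2Rb" = 1, "gc" = 1))
  y0 <- steady_state(pr, net, gc_default_traffic)
  trj <- simulate_protocol(y0, single_dose("IL-2", 0, seq(0, 500, by = 100)),
                           net, gc_default_rates, gc_default_traffic,
                           synthesis = pr$synthesis)
  drift <- apply(trj$states, 2, function(col) max(abs(col - col[1])))
  expect_lt(max(drift) / max(y0), 1e-6)
})

test_that("solution is converged with respect to solver tolerance", {
  net <- build_network("IL-2")
  pr <- cell_profile("x", synthesis = c("IL-2Ra" = 1.2, "IL-2Rb" = 0.6,
                                        "gc" = 2))
  y0 <- steady_state(pr, net, gc_default_traffic)
  prot <- single_dose("IL-2", 1, c(0, 500))
  run <- function(rt) {
    trj <- simulate_protocol(y0, prot, net, gc_default_rates,
                             gc_default_traffic, synthesis = pr$synthesis,
                             rtol = rt, atol = rt * 1e3)
    utils::tail(active_signal(trj, "IL-2"), 1)
  }
  expect_equal(run(1e-9), run(5e-10), tolerance = 1e-6)
})

test_that("active_signal sums the labeled active species in both compartments", {
  full <- build_network(GC_LIGANDS)
  pr <- cell_profile("x", surface = c(
    "IL-2Ra" = 1000, "IL-2Rb" = 800, "gc" = 2000, "IL-15Ra" = 300,
    "IL-4Ra" = 400, "IL-7Ra" = 1500, "IL-9R" = 200, "IL-21Ra" = 100))
  tr <- gc_default_traffic
  y0 <- initial_state(pr, full, tr)
  ev <- protocol(data.frame(ligand = c("IL-2", "IL-7"),
                            concentration_nM = c(0.5, 0.2),
                            onset_min = c(0, 0)), c(0, 30, 60))
  trj <- simulate_protocol(y0, ev, full, gc_default_rates, tr,
                           synthesis = synthesis_from_surface(pr$surface, tr))
  # brute-force sum over the labeled 62-species state
  for (lg in c("IL-2", "IL-7")) {
    labs <- active_species(full, lg)
    manual <- rowSums(trj$states[, paste0("surf/", labs), drop = FALSE]) +
      tr$phi * rowSums(trj$states[, paste0("endo/", labs), drop = FALSE])
    expect_equal(active_signal(trj, lg), manual, tolerance = 1e-12)
  }
  # un-stimulated family members stay silent
  expect_equal(max(active_signal(trj, "IL-4")), 0)
  expect_equal(max(active_signal(trj, "IL-21")), 0)
})

test_that("pstat applies a positive scalar", {
  expect_equal(pstat(c(10, 20), 0.5), c(5, 10))
  expect_equal(pstat(c(1, 2)), c(1, 2))
  expect_equal(pstat(c(1, 2), 2), 2 * pstat(c(1, 2), 1))
  expect_error(pstat(1:3, 0), "positive")
  expect_error(pstat(1:3, -1), "positive")
})

test_that("surface receptor depletion is dose dependent", {
  net <- build_network("IL-2")
  pr <- default_archetypes()$Treg
  tr <- gc_default_traffic
  y0 <- initial_state(pr, net, tr)
  syn <- synthesis_from_surface(pr$surface, tr)
  frac_at <- function(dose) {
    trj <- simulate_protocol(y0, single_dose("IL-2", dose, c(0, 60, 240)),
                             net, gc_default_rates, tr, synthesis = syn)
    surface_fraction(trj, "IL-2Rb")
  }
  f0 <- frac_at(0); f_low <- frac_at(0.001); f_high <- frac_at(1)
  expect_equal(f0[1], 100)
  expect_equal(unname(f0), c(100, 100, 100), tolerance = 1e-6)
  # monotone decrease, steeper at the higher dose
  expect_lt(f_high[2], f_low[2])
  expect_lt(f_high[3], f_high[2])
  expect_error({
    trj <- simulate_protocol(y0, single_dose("IL-2", 1, c(0, 60)), net,
                             gc_default_rates, tr, synthesis = syn)
    surface_fraction(trj, "IL-9R")
  }, "unknown receptor")
})

test_that("cross-inhibition is asymmetric when gc-dimerization Ka differs", {
  profs <- default_archetypes()
  ci0 <- cross_inhibition(profs$Thelper, "IL-7", 0, "IL-4", 0.00625)
  expect_equal(ci0$percent_inhibition, 0)

  # same-ligand pretreatment at saturating dose stays bounded by 100
  ci_self <- cross_inhibition(profs$Thelper, "IL-4", 50, "IL-4", 0.00625)
  expect_lte(ci_self$percent_inhibition, 100)

  # Ka(IL-7 -> gc) > Ka(IL-4 -> gc) under the defaults, so IL-7 pretreatment
  # inhibits IL-4 more than the reverse at matched pre-doses
  r <- gc_default_rates
  expect_lt(r$rev[["k_27_rev"]], r$rev[["k_33_rev"]])
  ci_74 <- cross_inhibition(profs$Thelper, "IL-7", 1, "IL-4", 0.00625)
  ci_47 <- cross_inhibition(profs$Thelper, "IL-4", 1, "IL-7", 0.002)
  expect_gt(ci_74$percent_inhibition, ci_47$percent_inhibition)
})

test_that("dose-response grid is consistent with direct simulation", {
  pr <- default_archetypes()$Treg
  tens <- dose_response_grid(list(pr), "IL-2", 0.1, 60, scale = 2)
  expect_equal(dim(tens), c(1, 1, 1))
  net <- build_network("IL-2")
  tr <- gc_default_traffic
  trj <- simulate_protocol(initial_state(pr, net, tr),
                           single_dose("IL-2", 0.1, c(0, 60)), net,
                           gc_default_rates, tr,
                           synthesis = synthesis_from_surface(pr$surface, tr))
  direct <- pstat(utils::tail(active_signal(trj, "IL-2"), 1), 2)
  expect_equal(unname(tens[1, 1, 1]), direct, tolerance = 1e-9)
})

test_that("grid responses rise monotonically with dose at 30 min", {
  profs <- default_archetypes()[c("Treg", "NK")]
  doses <- 10^seq(-3, 1, length.out = 6)
  tens <- dose_response_grid(profs, "IL-2", doses, c(30))
  expect_equal(dim(tens), c(1, 2, 6))
  for (i in 1:2) expect_true(all(diff(tens[1, i, ]) > -1e-9))
})

test_that("binding-only simulation converges to the algebraic equilibrium", {
  net <- build_network("IL-2")
  r <- gc_default_rates
  tr <- no_trafficking()
  at <- 2000; bt <- 700; gt <- 2500; L <- 0.25
  y0 <- empty_state(net)
  y0["surf/IL-2Ra"] <- at; y0["surf/IL-2Rb"] <- bt; y0["surf/gc"] <- gt
  trj <- simulate_protocol(y0, single_dose("IL-2", L, c(0, 20000)), net, r, tr)
  eq <- oracle_il2_equilibrium(L, at, bt, gt, r)
  final <- trj$states[2, paste0("surf/", names(eq))]
  expect_equal(unname(final), unname(eq), tolerance = 1e-6)
})
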