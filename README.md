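# gckin — binding and trafficking kinetics of the common γ-chain cytokines

The interleukins IL-2, IL-15, IL-4, IL-7, IL-9 and IL-21 all signal through
the shared common γ-chain (γc) receptor: each ligand binds its private
receptor(s), the complex recruits γc, and complexes carrying two
JAK-binding chains phosphorylate STAT5/STAT6. Which immune cells respond to
which dose of which ligand is set by their receptor expression — regulatory
T cells are sensitized to picomolar IL-2 by IL-2Rα, NK cells respond
through abundant IL-2Rβ, helper T cells through IL-7Rα — and by receptor
trafficking, which strips signaling complexes from the cell surface within
minutes. `gckin` is for quantitative immunologists and cytokine engineers
who want to simulate, fit and dissect this system: predicting cell-type-
specific pSTAT responses to natural ligands and engineered IL-2 variants
(muteins), and mapping the response space with tensor factorization.

## The model

A deterministic mass-action ODE system over every receptor/complex species
of the selected ligands, in two compartments (surface, endosome):

* ligand association: d[L·R]/dt gains k_bnd·[L]·[R] with
  k_bnd = 0.6 nM⁻¹min⁻¹ (10⁷ M⁻¹s⁻¹); dimerization steps share one forward
  rate k_fwd; each reverse rate k_i,rev is separate, with every closed
  binding cycle constrained to a unit product of equilibrium constants
  (detailed balance, e.g. k₁₂ = k₁k₁₁/k₂)
* trafficking: dE/dt = −kE + k_rec(1−f)·I·φ,
  dI/dt = kE/φ − k_rec(1−f)·I − k_deg·f·I, with k = k_endo or k_endo,a
  (active complexes, ~10× faster), sorting fraction f = f_sort (inactive)
  or 1 (active), and φ = 0.5 the relative endosomal membrane area
* endosomal ligand (10 fL volume) rebinds receptors or degrades; all
  endosomal dissociation rates carry a 5× acidic-pH penalty; extracellular
  ligand is clamped
* pSTAT prediction = (active complexes, surface + φ·endosomal) × a fitted
  scalar

On top of the simulator: Bayesian MCMC fitting with lognormal(σ_log = 0.1)
/ Beta(20,40) priors and Geweke diagnostics, Hill EC50 extraction,
Treg-specificity metrics with per-rate sensitivities, mutein affinity
overrides, and non-negative CP/Tucker decomposition of time × cell ×
condition response tensors.

## Worked example

```r
library(gckin)

profiles <- default_archetypes()          # 10 synthetic immune archetypes
rates    <- default_rate_table()
traffic  <- trafficking_params()

## Treg dose-response to IL-2, 1 h readout
doses <- 10^seq(-4, 1.5, length.out = 10)
net <- build_network("IL-2")
y0  <- initial_state(profiles$Treg, net, traffic)
syn <- synthesis_from_surface(profiles$Treg$surface, traffic)
resp <- sapply(doses, function(d) {
  tr <- simulate_protocol(y0, single_dose("IL-2", d, c(0, 60)),
                          net, rates, traffic, synthesis = syn)
  tail(active_signal(tr, "IL-2"), 1)
})
fit_hill(doses, resp)
#> Hill fit: EC50 = 0.03373 nM, n = 0.614, amplitude = 467.4, baseline = 1.197

## Tregs outcompete NK cells at low dose, not at high dose
predict_specificity(profiles, "Treg", "NK", dose_nM = 0.01)$specificity
#> [1] 2.493724
predict_specificity(profiles, "Treg", "NK", dose_nM = 10)$specificity
#> [1] 0.9714688

## factor the predicted response space
tens <- dose_response_grid(profiles, c("IL-2", "IL-15", "IL-7"),
                           10^seq(-3, 1, length.out = 4),
                           seq(0, 240, length.out = 13))
fit <- nncp(unclass(variance_scale(tens)), rank = 3, seed = 0)
fit
#> non-negative CP: rank 3, R2X = 0.9881 (5 restarts)
```

The EC50 of ~34 pM reflects the high-affinity trimeric IL-2 receptor on
IL-2Rα-high cells; the specificity ratio >1 at 10 pM and ~1 at 10 nM is the
dose window exploited by low-dose IL-2 therapy; and three CP components
capture ~99% of the predicted response tensor, separating an IL-7/helper
axis from high- and low-dose IL-2/15 axes.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/gckin.R synth  --seed 1 --out fixtures/
Rscript inst/cli/gckin.R factor --rank 3 --out factors/
```

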