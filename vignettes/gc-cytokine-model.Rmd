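---
title: "A binding and trafficking model of the common gamma-chain cytokine family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A binding and trafficking model of the common gamma-chain cytokine family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gckin)
```

## The model

The cytokines IL-2, IL-15, IL-4, IL-7, IL-9 and IL-21 all signal through the
shared common gamma chain (gc). Each ligand first binds a private receptor —
IL-2 and IL-15 additionally bind a signaling-deficient alpha chain (IL-2Ra /
IL-15Ra) and share the signaling-competent IL-2Rb — and the resulting
complexes recruit gc. Any complex carrying two signaling-competent,
JAK-binding chains (IL-2Rb, IL-4Ra, IL-7Ra, IL-9R, IL-21Ra, gc) is an
*active* complex; the number of active complexes, times a fitted scalar, is
the model's prediction of phosphorylated STAT (pSTAT5, or pSTAT6 for IL-4).

`gckin` implements this family as a deterministic mass-action ODE system in
two compartments (plasma membrane and a single endosomal compartment),
coupled by first-order trafficking:

* receptors and complexes are counted in molecules per cell; soluble ligand
  in nM. Ligand association uses one rate constant,
  `k_bnd = 0.6 nM^-1 min^-1` (1e7 M^-1 s^-1); all receptor dimerization
  steps share one forward rate `k_fwd` (units cell/#/min); each reverse rate
  is its own constant (min^-1).
* inactive species are endocytosed at `k_endo`, active species at
  `k_endo_active`; a fraction `f_sort` of inactive endosomal species sorts
  to the lysosome (degraded at `k_deg`), the remainder recycles at `k_rec`;
  active species sort with fraction 1. Endosomal species are stored
  area-normalized: the endosomal membrane has fraction `phi = 0.5` of the
  plasma-membrane area, so total endosomal molecules are `phi` times the
  stored value, and per-chain mass `surface + phi * endosomal` is conserved
  when synthesis and degradation are off.
* free endosomal ligand (10 fL volume; 6.022 molecules ~ 1 nM) is produced
  by endosomal dissociation, rebinds endosomal receptors, and degrades at
  `k_deg` with sorting fraction 1. Extracellular ligand is clamped: the
  medium is treated as an infinite reservoir, matching the absence of a
  ligand-depletion equation in the model's formulation (depletion would
  require a cell density that is not part of the model).
* all endosomal reverse rates carry a uniform 5-fold penalty (acidic pH).

A note on naming: in the trafficking equations, the species depleted by
endocytosis is the *surface* species and the species receiving it the
*endosomal* one; the package resolves the compartments by that equation
structure throughout.

## Detailed balance

Closed cycles in the binding graph (e.g. ligand binding alpha then
dimerizing beta, versus binding beta then dimerizing alpha) must have unit
products of equilibrium constants. With a single `k_fwd` this reduces to
relations among reverse rates, and the binding graph of an alpha-bearing
ligand (7 complexes, 9 reverse rates) has exactly three independent cycles,
so exactly three reverse rates are derived:

* IL-2: `k12 = k1*k11/k2`, `k8 = k10*k12/k5`, `k9 = k10*k11/k4` — with the
  binary affinities (`k1`, `k2`) fixed from literature KDs and `k5`, `k10`,
  `k11` fixed at experimentally measured dissociation rates, leaving `k4`
  (and `k_fwd`) free.
* IL-15: the analogous relations with `k22` (gc dissociation from the
  quaternary complex) taking the role of the experimentally fixed `k10`;
  `k16`, `k17`, `k22`, `k23` are free and `k20`, `k21`, `k24` derived. Only
  three rates can be dependent here — a fourth derived slot would
  over-determine the three-cycle graph.

`enforce_detailed_balance()` re-derives the dependent slots and is called
automatically whenever rates change (parameter proposals during fitting,
mutein overrides).

## Default parameter values

Literature-fixed constants: binary KDs of 10 / 144 / 0.065 / 438 nM for
IL-2.IL-2Ra, IL-2.IL-2Rb, IL-15.IL-15Ra, IL-15.IL-2Rb and 1.0 / 59 / 0.1 /
0.07 nM for IL-4 / IL-7 / IL-9 / IL-21 binding their private receptors;
`k5 = 1.5`, `k10 = 12`, `k11 = 63` min^-1.

The free rates have no published point values (they are posteriors in the
original fits), so the package ships documented defaults, flagged `fitted`
in the rate table, chosen once on physiological grounds:

* `k_fwd = 0.1` cell/#/min places predicted IL-2 EC50s of IL-2Ra-high cells
  in the tens-of-pM range where such cells respond; much smaller values
  leave the model insensitive below nM doses.
* IL-15's free reverse rates default to their IL-2 analogues, reflecting
  the generally similar dimerization affinities of the two ligands.
* `k_27_rev = 0.3` vs `k_33_rev = 30` min^-1 gives IL-7.IL-7Ra a ~100-fold
  larger gc-dimerization Ka than IL-4.IL-4Ra. The gap must be large because
  IL-4 binds its private receptor ~59x more tightly than IL-7 binds its
  own; only a strong gc-affinity advantage lets IL-7 pretreatment inhibit
  IL-4 signaling more than the reverse, the behavior this family exhibits.
* trafficking: `k_endo = 0.01` min^-1 (surface half-life ~70 min, typical
  of constitutive receptor turnover), `k_endo_active = 0.1` (active
  complexes internalize ~10x faster), `f_sort = 1/3` (the mean of its
  Beta(20, 40) prior), `k_rec = 0.1`, `k_deg = 0.03` min^-1.

These defaults are the synthetic-data generator's "true" parameters and the
centers of the default priors; they were fixed before the test suite was
written and are not tuned per analysis.

## Simulation and readouts

Cells are initialized at the closed-form no-ligand steady state: for each
free receptor with synthesis rate `v`,
`E = v (k_rec(1-f) + k_deg f) / (k_endo k_deg f)` on the surface and
`I = k_endo E / (phi (k_rec(1-f) + k_deg f))` in the endosome.
`synthesis_from_surface()` inverts this exactly, which is how measured
surface abundances enter the model. Stimulation protocols are integrated
with a stiff solver (lsoda, relative tolerance 1e-9 by default; likelihood
evaluations use 1e-5, which changes a 500-min response by well under one
part in 1e4), restarting at each stimulus onset with the ligand clamped to
its new concentration — pretreatment cytokines remain present when a second
stimulus is added.

Readouts: `active_signal()` (surface active complexes plus `phi` times
endosomal ones — endosomal complexes are assumed to keep signaling at full
weight, configurable via `endosomal_weight`), `pstat()` (scalar scaling),
`surface_fraction()` (percent-of-initial surface receptor),
`cross_inhibition()` (10-min pretreatment, 10-min co-stimulation by
default) and `dose_response_grid()` (labeled time x cell x condition
tensor).

## Inference

The likelihood is Gaussian on the residual sum of squares, one noise scale
per scale group; sigma may be fitted under a weak half-normal prior or
fixed — fixing it at the known generating noise keeps the reduced recovery
fit at exactly six structural parameters. Priors are lognormal with
log-scale sd 0.1 around the documented defaults (`f_sort` ~ Beta(20, 40)).
Sampling uses adaptive random-walk Metropolis on the unconstrained scale
(log, or logit for `f_sort`) with Jacobian corrections; the proposal
covariance adapts only during warm-up (frozen afterwards, so the retained
chain is a valid Metropolis sampler), and every run is reproducible from
its seed. Convergence is checked with the Geweke diagnostic (first 10% vs
last 50%, spectral-density variances from an AR fit; |z| < 2). Posterior
predictive bands use 100 draws and report 10/25/75/90% pointwise quantiles.

The no-trafficking variant zeroes all trafficking rates; receptor abundance
is then a directly specified constant and signaling is surface binding
equilibrium only. Refitting trafficking-generated data with this variant
prefers systematically smaller receptor numbers — the variant must shrink
the receptor pool to mimic the depletion that trafficking produces — which
is why it generalizes poorly to cells whose receptor counts are measured.

## Tensor decomposition

`dose_response_grid()` tensors are variance-scaled per cell population
(each cell slice divided by the standard deviation of its entries, so
strongly and weakly responding cells contribute comparably) and decomposed
with non-negative CP (HALS updates, 5 seeded random restarts, relative
tolerance 1e-7) or non-negative Tucker (multiplicative updates). When all
Tucker ranks equal the CP rank, the CP solution seeds one Tucker restart —
CP is a Tucker model with superdiagonal core — so the Tucker fit can never
fall below the CP fit at matched ranks. Receptor-abundance PCA uses
log10(x+1) counts centered per receptor, since abundances span decades.
Factor correspondence between decompositions uses greedy maximum-cosine
column pairing.

On the bundled ten archetypes stimulated with IL-2, IL-15 and IL-7 (4
log-spaced doses from 1 pM to 10 nM, 13 time points over 0-240 min), three
components capture ~99% of the variance-scaled prediction tensor
(`scripts/acceptance.R` recomputes this; rank 2 gives ~97%, rank 1 ~83%).

## Specificity metrics and muteins

Cell-type specificity is the ratio of the target cell's pSTAT to an
off-target cell's at a stated dose and time (defaults 38 pM, 60 min), with
each cell first normalized to its own maximum over the dose series (the
normalization used before such ratios is not uniquely determined; per-cell
max is the package's documented choice, and `normalize = "none"` disables
it). The ratio is invariant to the pSTAT scalar either way.

`specificity_gradient()` differentiates specificity with respect to the
natural log of each reverse rate — surface and endosomal copies varied
independently — by central differences at relative step 1e-2, cross-checked
against 1e-3 and warning on >1% disagreement. Rates are perturbed one at a
time without re-imposing detailed balance, so each number isolates a single
kinetic step.

Engineered IL-2 variants (muteins) are described by measured KDs for
IL-2Ra and for the pre-dimerized IL-2Rb/gc heterodimer. The alpha KD
fold-change maps directly onto `k_1_rev`; the composite beta/gc KD cannot
be uniquely attributed to one step, so its fold-change is applied uniformly
to `k_2_rev` and the IL-2 gc-dimerization reverse rates (`k_4/k_5/k_10`),
after which detailed balance is re-enforced. Hill fits
(`baseline + amplitude * x^n / (EC50^n + x^n)`) are unbounded; negative
fitted baselines are reported, not clipped.

## Synthetic data

`default_archetypes()` ships ten receptor profiles spanning the family's
qualitative expression patterns — Tregs with high IL-2Ra, helper T cells
with high IL-7Ra, NK cells with high IL-2Rb and low gc, CD8 cells
intermediate, plus naive/memory interpolations and modest IL-4Ra on all
types. These are fixture constants chosen to reproduce the qualitative
ordering of measured immune profiles, not measurements. `synth_generate()`
simulates pSTAT tables at the default ("true") parameters and applies
mean-one multiplicative lognormal noise (`sdlog = sqrt(log(1+cv^2))`,
default CV 0.10). What the generator does *not* emulate: cell-to-cell
variability within a population, downstream JAK-STAT dynamics, receptor
shedding, or ligand depletion from the medium — so passing recovery tests
demonstrate correctness of the inference machinery under the model's own
assumptions, not robustness to those real-data features.

## Numerical choices and limitations

* Problem sizes: the full six-ligand network has 28 receptor species per
  compartment (62 dynamic states); the bundled analyses use the ligand
  subsets they need. The reduced recovery fit uses one cell type, six
  doses, two time points and 2 chains x 1000 draws — sizes chosen so the
  whole suite runs comfortably on a laptop while keeping every check
  informative.
* The integrator may produce harmless sub-tolerance negative values at the
  zero boundary; fluxes are evaluated on clamped-at-zero states and
  trajectories are clipped at zero.
* NNCP columns that collapse to zero during HALS are re-seeded at 1e-12 to
  keep the requested rank; tie-breaking across restarts is by best R2X.
* Deterministic mass action only: no stochastic simulation, no
  pH-dependence beyond the single 5-fold endosomal penalty, no
  pharmacokinetics or autocrine ligand.
* IL-9 and IL-21 are included topologically with literature binary KDs but
  excluded from default fitting; their gc-dimerization defaults are
  order-of-magnitude placeholders.
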