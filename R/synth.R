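# Synthetic fixtures: receptor-abundance archetypes spanning the family's
# qualitative expression patterns, and noisy pSTAT dose-response tables
# simulated from known parameters. Everything downstream (fitting, tensor
# factorization, metrics) is testable against these without external data.

#' Built-in immune cell archetypes
#'
#' Ten receptor-abundance profiles (#/cell) spanning the qualitative
#' patterns of circulating immune cells: regulatory T cells with high
#' IL-2Ra, helper T cells with high IL-7Ra, NK cells with high IL-2Rb and
#' comparatively low gc, CD8 T cells intermediate, plus naive/memory
#' interpolations. These are fixture constants, not measurements.
#'
#' @return Named list of `gc_profile`s (surface abundances).
#' @export
default_archetypes <- function() {
  tab <- rbind(
    Treg          = c(3000,  700, 3000, 100,  500, 400),
    Treg_memory   = c(2000,  800, 2800, 120,  700, 350),
    Treg_naive    = c(2500,  500, 2600,  80,  900, 300),
    Thelper       = c( 300,  600, 2500, 100, 2000, 500),
    Thelper_mem   = c( 400,  700, 2400, 120, 1800, 450),
    Thelper_naive = c( 150,  500, 2300,  80, 2200, 400),
    CD8           = c( 100, 1500, 2000, 200, 1200, 300),
    CD8_memory    = c( 400, 1200, 2200, 180, 1000, 350),
    NK            = c(  50, 5000,  800, 300,  200, 150),
    NKT           = c(  80, 3000, 1200, 250,  400, 200))
  colnames(tab) <- c("IL-2Ra", "IL-2Rb", "gc", "IL-15Ra", "IL-7Ra", "IL-4Ra")
  profs <- lapply(rownames(tab), function(nm)
    cell_profile(nm, surface = tab[nm, ]))
  stats::setNames(profs, rownames(tab))
}

#' Configuration for the synthetic fixture generator
#'
#' @param archetypes Named list of `gc_profile`s (default
#'   [default_archetypes()]).
#' @param ligands Ligands to stimulate with.
#' @param doses Dose grid (nM).
#' @param times Time grid (min).
#' @param cv Multiplicative lognormal noise coefficient of variation
#'   (default 0.10; 0 gives noise-free tables).
#' @param rates,traffic Generating ("true") parameters.
#' @param scale pSTAT scale factor applied to active-complex counts.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return List of class `gc_synth_config`.
#' @export
synth_config <- function(archetypes = default_archetypes(),
                         ligands = c("IL-2", "IL-15", "IL-7"),
                         doses = 10^seq(-3, 1, length.out = 4),
                         times = c(30, 60, 120, 240),
                         cv = 0.10,
                         rates = default_rate_table(),
                         traffic = trafficking_params(),
                         scale = 1, seed = 1) {
  if (cv < 0) stop("cv must be >= 0")
  structure(list(archetypes = archetypes, ligands = ligands, doses = doses,
                 times = times, cv = cv, rates = rates, traffic = traffic,
                 scale = scale, seed = seed), class = "gc_synth_config")
}

#' Generate synthetic receptor and dose-response tables
#'
#' Simulates every (cell, ligand, dose, time) condition at the configured
#' true parameters and applies multiplicative lognormal noise with the
#' configured CV (mean-one: `meanlog = -sdlog^2/2`,
#' `sdlog = sqrt(log(1+cv^2))`). The truth record stores the generating
#' parameters so recovery tests can compare against them.
#'
#' @param config A `gc_synth_config`.
#' @param replicates Replicates per condition (default 2).
#' @return List: `receptor_table` (data.frame), `response_table`
#'   (data.frame), `truth` (generating parameters and the noise-free
#'   predictions), `tensor` (noise-free `response_tensor`).
#' @export
synth_generate <- function(config, replicates = 2) {
  stopifnot(inherits(config, "gc_synth_config"))
  set.seed(config$seed)
  profs <- config$archetypes
  rec <- do.call(rbind, lapply(profs, function(p)
    data.frame(cell_type = p$name, receptor = names(p$surface),
               count = as.numeric(p$surface))))
  rownames(rec) <- NULL
  grid_times <- sort(unique(c(0, config$times)))
  tensor <- dose_response_grid(profs, config$ligands, config$doses,
                               grid_times, rates = config$rates,
                               traffic = config$traffic, scale = config$scale)
  conds <- attr(tensor, "conditions")
  sdlog <- sqrt(log(1 + config$cv^2))
  rows <- list()
  for (i in seq_along(profs)) for (j in seq_len(nrow(conds)))
    for (tm in config$times) {
      mu <- tensor[as.character(tm), i, j]
      for (rp in seq_len(replicates)) {
        noise <- if (config$cv == 0) 1
                 else stats::rlnorm(1, -sdlog^2 / 2, sdlog)
        rows[[length(rows) + 1]] <- data.frame(
          cell_type = profs[[i]]$name, ligand = conds$ligand[j],
          concentration_nM = conds$concentration_nM[j], time_min = tm,
          readout = "pSTAT", value = mu * noise, replicate = rp)
      }
    }
  resp <- do.call(rbind, rows)
  list(receptor_table = rec, response_table = resp,
       truth = list(rates = config$rates, traffic = config$traffic,
                    scale = config$scale, cv = config$cv, seed = config$seed),
       tensor = tensor)
}
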