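#' Unit conversions between molecule counts and endosomal concentration
#'
#' Converts a number of molecules per cell confined to the endosomal volume
#' (default 10 fL) into a concentration in nM, and back. Used internally to
#' couple endosomal free-ligand concentration to receptor-complex counts.
#'
#' @param count Molecules per cell (non-negative).
#' @param v_endo_fL Endosomal volume in femtoliters.
#' @return Concentration in nM (`count_to_nM`) or molecule count
#'   (`nM_to_count`).
#' @examples
#' count_to_nM(6.022)          # ~1 nM in a 10 fL endosome
#' nM_to_count(count_to_nM(1)) # round trip
#' @export
count_to_nM <- function(count, v_endo_fL = 10) {
  if (any(count < 0)) stop("molecule count must be non-negative")
  if (v_endo_fL <= 0) stop("endosomal volume must be positive")
  # nM = count / (N_A * V[L]) * 1e9 ; with V = v_fL * 1e-15 L this reduces to
  # count / (0.602214076 * v_fL)
  count / (0.602214076 * v_endo_fL)
}

#' @rdname count_to_nM
#' @param conc_nM Concentration in nM.
#' @export
nM_to_count <- function(conc_nM, v_endo_fL = 10) {
  if (any(conc_nM < 0)) stop("concentration must be non-negative")
  if (v_endo_fL <= 0) stop("endosomal volume must be positive")
  conc_nM * 0.602214076 * v_endo_fL
}
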