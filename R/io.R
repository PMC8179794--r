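# Tabular interchange. CSV throughout; JSON manifests carry axis labels.

GC_RECEPTORS <- c("IL-2Ra", "IL-2Rb", "gc", "IL-15Ra", "IL-4Ra", "IL-7Ra",
                  "IL-9R", "IL-21Ra")

#' Read a per-cell-type receptor abundance table
#'
#' Expected CSV columns: `cell_type`, `receptor`, `count` and optionally
#' `sem`. Receptor names must be drawn from the family's chains
#' (IL-2Ra, IL-2Rb, gc, IL-15Ra, IL-4Ra, IL-7Ra, IL-9R, IL-21Ra).
#'
#' @param path CSV path.
#' @return Named list of `gc_profile`s (surface abundances).
#' @export
read_receptor_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "receptor", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(list())
  bad <- which(!df$receptor %in% GC_RECEPTORS)
  if (length(bad) > 0)
    stop("unknown receptor '", df$receptor[bad[1]], "' at row ", bad[1])
  neg <- which(df$count < 0)
  if (length(neg) > 0)
    stop("negative count at row ", neg[1])
  profs <- lapply(split(df, df$cell_type), function(sub)
    cell_profile(sub$cell_type[1],
                 surface = stats::setNames(sub$count, sub$receptor)))
  profs[unique(df$cell_type)]
}

#' @rdname read_receptor_table
#' @param profiles Named list of `gc_profile`s.
#' @return `write_receptor_table` returns `path` invisibly.
#' @export
write_receptor_table <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    surf <- p$surface
    if (is.null(surf)) stop("profile ", p$name, " has no surface abundances")
    data.frame(cell_type = p$name, receptor = names(surf),
               count = as.numeric(surf))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response measurement table
#'
#' Expected CSV columns: `cell_type`, `ligand`, `concentration_nM`,
#' `time_min`, `readout`, `value`, `replicate` (optional `scale_group`,
#' defaulting to the readout). Duplicate
#' (cell, ligand, concentration, time, readout, replicate) rows are
#' rejected.
#'
#' @param path CSV path.
#' @param profiles Named list of `gc_profile`s covering the table's cells.
#' @return A `gc_fitdata`.
#' @export
read_response_table <- function(path, profiles) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "ligand", "concentration_nM", "time_min", "readout",
            "value", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(df$cell_type, df$ligand, df$concentration_nM,
                     df$time_min, df$readout, df$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate observation at row ", which(duplicated(key))[1])
  fit_dataset(df, profiles)
}

#' Write a response table
#' @param data A `gc_fitdata` or observations data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(data, path) {
  obs <- if (inherits(data, "gc_fitdata")) data$obs else data
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory as tidy CSV
#'
#' Long format: `time_min`, `compartment` (surf/endo/ext), `species`,
#' `abundance` (#/cell for receptor species; nM for ligand states).
#'
#' @param traj A `gc_trajectory`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  nm <- colnames(traj$states)
  comp <- sub("/.*$", "", nm)
  species <- sub("^[a-z]+/", "", nm)
  long <- data.frame(
    time_min = rep(traj$times, times = length(nm)),
    compartment = rep(comp, each = length(traj$times)),
    species = rep(species, each = length(traj$times)),
    abundance = as.vector(traj$states))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
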