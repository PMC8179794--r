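# Non-negative tensor factorization of labeled response tensors, plus PCA of
# receptor profiles. Non-negative CP uses hierarchical alternating least
# squares (HALS) column updates with seeded random restarts; non-negative
# Tucker uses multiplicative updates, seeded from the best CP solution (a CP
# model is a Tucker model with superdiagonal core, so Tucker fit quality can
# never fall below CP at matched ranks).

# ---- small multilinear-algebra helpers ----------------------------------

# mode-n unfolding: rows = mode n, columns = remaining modes ascending with
# the first remaining mode varying fastest (column-major convention)
unfold <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, seq_along(d)[-mode])
  matrix(aperm(x, perm), nrow = d[mode])
}

refold <- function(m, mode, dims) {
  perm <- c(mode, seq_along(dims)[-mode])
  x <- array(m, dim = dims[perm])
  aperm(x, order(perm))
}

# columnwise Khatri-Rao over a list of factor matrices, first-listed mode
# varying fastest (matches the unfolding convention above)
khatri_rao_list <- function(mats) {
  out <- matrix(1, 1, ncol(mats[[1]]))
  for (m in mats)
    out <- vapply(seq_len(ncol(m)), function(r) kronecker(m[, r], out[, r]),
                  numeric(nrow(out) * nrow(m)))
  out
}

# tensor-times-matrix along a mode
ttm <- function(x, mat, mode) {
  d <- dim(x)
  m <- mat %*% unfold(x, mode)
  d[mode] <- nrow(mat)
  refold(m, mode, d)
}

cp_reconstruct <- function(factors) {
  d <- vapply(factors, nrow, integer(1))
  m <- factors[[1]] %*% t(khatri_rao_list(factors[-1]))
  refold(m, 1, d)
}

tucker_reconstruct <- function(core, factors) {
  x <- core
  for (n in seq_along(factors)) x <- ttm(x, factors[[n]], n)
  x
}

# ---- operations ----------------------------------------------------------

#' Variance-scale a response tensor across cell populations
#'
#' Divides each cell type's slice by the standard deviation of that slice's
#' entries (computed over all other modes), giving every cell population unit
#' variance so that strongly and weakly responding cells contribute equally
#' to the decomposition.
#'
#' @param tensor Array with a `cell` mode (named dimnames) or, failing that,
#'   with the cell mode given by `mode`.
#' @param mode Dimension holding cell types (default: the dim named "cell",
#'   else 2).
#' @return Tensor of the same shape and class.
#' @export
variance_scale <- function(tensor, mode = NULL) {
  dn <- dimnames(tensor)
  if (is.null(mode))
    mode <- if (!is.null(names(dn)) && "cell" %in% names(dn))
      which(names(dn) == "cell") else 2L
  u <- unfold(tensor, mode)
  sds <- apply(u, 1, stats::sd)
  if (any(sds == 0)) {
    labs <- if (!is.null(dn[[mode]])) dn[[mode]][sds == 0] else which(sds == 0)
    stop("zero-variance cell slice(s): ", paste(labs, collapse = ", "))
  }
  out <- refold(u / sds, mode, dim(tensor))
  dimnames(out) <- dn
  attributes(out) <- attributes(tensor)
  out
}

#' Fraction of tensor variation explained by a reconstruction
#'
#' `R2X = 1 - ||T - That||_F^2 / ||T||_F^2`.
#'
#' @param tensor Reference tensor (non-zero).
#' @param reconstruction Same-shape array.
#' @return Scalar in (-Inf, 1].
#' @export
r2x <- function(tensor, reconstruction) {
  if (!identical(dim(tensor), dim(reconstruction)))
    stop("tensor and reconstruction shapes differ")
  ss <- sum(tensor^2)
  if (ss == 0) stop("reference tensor is identically zero")
  1 - sum((tensor - reconstruction)^2) / ss
}

#' Non-negative canonical polyadic (CP) decomposition
#'
#' Approximates a non-negative tensor by a sum of `rank` rank-1 outer
#' products with non-negative factor matrices, fitted by hierarchical
#' alternating least squares with seeded random restarts; the best restart
#' (highest R2X) is returned.
#'
#' @param tensor Non-negative array (any number of modes >= 2).
#' @param rank Number of components (must not exceed any mode dimension).
#' @param seed Integer seed for the restarts.
#' @param restarts Number of random initializations.
#' @param tol Relative R2X change convergence tolerance.
#' @param max_iter Iteration cap per restart.
#' @return Object of class `gc_cp`: `factors` (one non-negative matrix per
#'   mode, labeled from dimnames), `rank`, `R2X`, `seed`, `iterations`.
#' @export
nncp <- function(tensor, rank, seed = 0, restarts = 5, tol = 1e-7,
                 max_iter = 10000) {
  if (any(tensor < 0)) stop("tensor must be non-negative")
  d <- dim(tensor)
  if (rank < 1) stop("rank must be >= 1")
  if (rank > min(d))
    stop("rank ", rank, " exceeds smallest mode dimension ", min(d))
  N <- length(d)
  unfoldings <- lapply(seq_len(N), function(n) unfold(tensor, n))
  normX2 <- sum(tensor^2)
  best <- NULL
  for (rs in seq_len(restarts)) {
    set.seed(seed + rs - 1L)
    A <- lapply(d, function(dn)
      matrix(stats::runif(dn * rank, 0.1, 1), dn, rank) * mean(abs(tensor)))
    grams <- lapply(A, crossprod)
    prev <- -Inf; it <- 0L
    repeat {
      it <- it + 1L
      for (n in seq_len(N)) {
        others <- seq_len(N)[-n]
        G <- Reduce(`*`, grams[others])           # Hadamard of Gram matrices
        V <- khatri_rao_list(A[others])
        W <- unfoldings[[n]] %*% V
        An <- A[[n]]
        for (r in seq_len(rank)) {
          num <- W[, r] - An %*% G[, r] + An[, r] * G[r, r]
          An[, r] <- pmax(num / max(G[r, r], 1e-30), 0)
          if (all(An[, r] == 0)) An[, r] <- 1e-12  # keep component alive
        }
        A[[n]] <- An
        grams[[n]] <- crossprod(An)
      }
      # fast fit: ||X-Xhat||^2 = ||X||^2 - 2<W, A_N> + sum(G_all)
      Gall <- Reduce(`*`, grams)
      err2 <- normX2 - 2 * sum(W * A[[N]]) + sum(Gall)
      fit <- 1 - max(err2, 0) / normX2
      if (it >= max_iter || (is.finite(prev) && abs(fit - prev) < tol)) break
      prev <- fit
    }
    if (is.null(best) || fit > best$R2X)
      best <- list(factors = A, R2X = fit, iterations = it, restart = rs)
  }
  dn <- dimnames(tensor)
  for (n in seq_len(N)) {
    rownames(best$factors[[n]]) <- if (!is.null(dn)) dn[[n]] else NULL
    colnames(best$factors[[n]]) <- paste0("comp", seq_len(rank))
  }
  if (!is.null(dn) && !is.null(names(dn))) names(best$factors) <- names(dn)
  structure(list(factors = best$factors, rank = rank, R2X = best$R2X,
                 seed = seed, restarts = restarts,
                 iterations = best$iterations, best_restart = best$restart),
            class = "gc_cp")
}

#' @exportS3Method print gc_cp
print.gc_cp <- function(x, ...) {
  cat(sprintf("non-negative CP: rank %d, R2X = %.4f (%d restarts)\n",
              x$rank, x$R2X, x$restarts))
  invisible(x)
}

#' Reconstruction from CP factors
#' @param fit A `gc_cp`.
#' @return Array of the original shape.
#' @export
cp_predict <- function(fit) cp_reconstruct(fit$factors)

#' Non-negative Tucker decomposition
#'
#' Fits a non-negative core tensor and per-mode non-negative factor matrices
#' by multiplicative updates. Initializations include seeded random restarts
#' and, when all ranks are equal, the corresponding CP solution (CP is a
#' Tucker model with superdiagonal core), which guarantees Tucker fit at
#' matched ranks is at least the CP fit.
#'
#' @param tensor Non-negative array.
#' @param ranks Integer vector of per-mode ranks.
#' @param seed Integer seed.
#' @param restarts Random restarts in addition to the CP initialization.
#' @param tol Relative fit-change tolerance.
#' @param max_iter Iteration cap.
#' @return Object of class `gc_tucker`: `core`, `factors`, `R2X`.
#' @export
ntucker <- function(tensor, ranks, seed = 0, restarts = 2, tol = 1e-7,
                    max_iter = 500) {
  if (any(tensor < 0)) stop("tensor must be non-negative")
  d <- dim(tensor)
  if (length(ranks) != length(d))
    stop("need one rank per mode (", length(d), " modes)")
  if (any(ranks < 1) || any(ranks > d))
    stop("ranks must lie between 1 and the mode dimensions (",
         paste(d, collapse = "x"), ")")
  N <- length(d)
  normX2 <- sum(tensor^2)
  eps <- 1e-12

  run_mu <- function(core, A) {
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      for (n in seq_len(N)) {
        others <- seq_len(N)[-n]
        # B = G_(n) * kron of other factors' transposes (via ttm chain)
        Bt <- core
        for (m in others) Bt <- ttm(Bt, A[[m]], m)
        Bn <- unfold(Bt, n)                       # ranks_n x prod(d[-n])
        Xn <- unfold(tensor, n)
        num <- Xn %*% t(Bn)
        den <- A[[n]] %*% (Bn %*% t(Bn))
        A[[n]] <- A[[n]] * num / pmax(den, eps)
      }
      numc <- tensor; denc <- core
      for (n in seq_len(N)) {
        numc <- ttm(numc, t(A[[n]]), n)
        denc <- ttm(denc, crossprod(A[[n]]), n)
      }
      core <- core * numc / pmax(denc, eps)
      fit <- 1 - sum((tensor - tucker_reconstruct(core, A))^2) / normX2
      if (is.finite(prev) && abs(fit - prev) < tol) break
      prev <- fit
    }
    list(core = core, factors = A, R2X = fit)
  }

  cands <- list()
  if (length(unique(ranks)) == 1) {
    cp <- nncp(tensor, ranks[1], seed = seed, restarts = 3)
    core <- array(0, dim = ranks)   # superdiagonal core: Tucker form of CP
    A <- cp$factors
    for (r in seq_len(ranks[1]))
      core[matrix(r, 1, N)] <- 1
    cands <- c(cands, list(list(core = core, A = A)))
  }
  for (rs in seq_len(restarts)) {
    set.seed(seed + 100L + rs)
    A <- lapply(seq_len(N), function(n)
      matrix(stats::runif(d[n] * ranks[n], 0.1, 1), d[n], ranks[n]))
    core <- array(stats::runif(prod(ranks), 0.1, 1), dim = ranks) *
      mean(abs(tensor))
    cands <- c(cands, list(list(core = core, A = A)))
  }
  best <- NULL
  for (cand in cands) {
    res <- run_mu(cand$core, cand$A)
    if (is.null(best) || res$R2X > best$R2X) best <- res
  }
  dn <- dimnames(tensor)
  for (n in seq_len(N)) {
    rownames(best$factors[[n]]) <- if (!is.null(dn)) dn[[n]] else NULL
    colnames(best$factors[[n]]) <- paste0("comp", seq_len(ranks[n]))
  }
  structure(list(core = best$core, factors = best$factors, R2X = best$R2X,
                 ranks = ranks, seed = seed), class = "gc_tucker")
}

#' @exportS3Method print gc_tucker
print.gc_tucker <- function(x, ...) {
  cat(sprintf("non-negative Tucker: ranks (%s), R2X = %.4f\n",
              paste(x$ranks, collapse = ","), x$R2X))
  invisible(x)
}

#' Reconstruction from Tucker factors
#' @param fit A `gc_tucker`.
#' @return Array of the original shape.
#' @export
tucker_predict <- function(fit) tucker_reconstruct(fit$core, fit$factors)

#' PCA of receptor abundance profiles
#'
#' Receptor counts span several decades, so the matrix is log10(x+1)
#' transformed and centered per receptor before the eigendecomposition.
#'
#' @param mat Numeric matrix, cells x receptors (>= 2 of each).
#' @param log_transform Apply the log10(x+1) transform (default TRUE).
#' @return List of class `gc_pca`: `scores` (cells x components), `loadings`
#'   (receptors x components, orthonormal), `explained` (variance fractions,
#'   non-increasing).
#' @export
pca_receptors <- function(mat, log_transform = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need at least 2 cells and 2 receptors")
  x <- if (log_transform) log10(mat + 1) else mat
  if (all(apply(x, 2, stats::var) == 0))
    stop("receptor matrix is constant; PCA undefined")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation, explained = expl,
                 center = p$center), class = "gc_pca")
}

#' Cosine similarity of matched factor components
#'
#' Pairs the columns of two factor matrices greedily by maximum cosine and
#' reports the cosine of each matched pair.
#'
#' @param a,b Factor matrices with equal row dimension.
#' @return data.frame `component_a`, `component_b`, `cosine`.
#' @export
factor_similarity <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("factor matrices have different row dimension")
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  if (any(na == 0) || any(nb == 0)) stop("zero column in factor matrix")
  cs <- crossprod(a, b) / outer(na, nb)
  out <- NULL
  avail_a <- seq_len(ncol(a)); avail_b <- seq_len(ncol(b))
  while (length(avail_a) > 0 && length(avail_b) > 0) {
    sub <- cs[avail_a, avail_b, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(component_a = avail_a[ij[1]],
                                 component_b = avail_b[ij[2]],
                                 cosine = sub[ij[1], ij[2]]))
    avail_a <- avail_a[-ij[1]]; avail_b <- avail_b[-ij[2]]
  }
  out
}

#' Serialize a 3-way response tensor to CSV slices plus a JSON manifest
#'
#' One CSV per cell-type slice (time rows x condition columns) and a
#' `manifest.json` holding axis labels.
#'
#' @param tensor A `response_tensor` (time x cell x condition).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_tensor <- function(tensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dn <- dimnames(tensor)
  files <- character(dim(tensor)[2])
  for (i in seq_len(dim(tensor)[2])) {
    f <- paste0("slice_", gsub("[^A-Za-z0-9_-]", "_", dn[[2]][i]), ".csv")
    files[i] <- f
    sl <- tensor[, i, , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = dim(tensor)[1])
    utils::write.csv(data.frame(time = dn[[1]], sl, check.names = FALSE),
                     file.path(dir, f), row.names = FALSE)
  }
  manifest <- list(axes = list(time = dn[[1]], cell = dn[[2]],
                               condition = dn[[3]]), slices = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ax <- manifest$axes
  arr <- array(NA_real_,
               dim = c(length(ax$time), length(ax$cell), length(ax$condition)),
               dimnames = list(time = ax$time, cell = ax$cell,
                               condition = ax$condition))
  for (i in seq_along(manifest$slices)) {
    df <- utils::read.csv(file.path(dir, manifest$slices[i]),
                          check.names = FALSE)
    arr[, i, ] <- as.matrix(df[, -1, drop = FALSE])
  }
  structure(arr, class = c("response_tensor", "array"))
}

#' Write CP factor matrices, one CSV per mode, with a JSON manifest
#' @param fit A `gc_cp`.
#' @param dir Output directory.
#' @return Invisibly, the written file names.
#' @export
write_factors <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  modes <- names(fit$factors)
  if (is.null(modes)) modes <- paste0("mode", seq_along(fit$factors))
  files <- character(length(modes))
  for (n in seq_along(fit$factors)) {
    files[n] <- paste0("factor_", modes[n], ".csv")
    utils::write.csv(data.frame(label = rownames(fit$factors[[n]]),
                                fit$factors[[n]], check.names = FALSE),
                     file.path(dir, files[n]), row.names = FALSE)
  }
  jsonlite::write_json(list(rank = fit$rank, R2X = fit$R2X, files = files),
                       file.path(dir, "factors.json"), auto_unbox = TRUE)
  invisible(files)
}
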