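# Bray-Curtis dissimilarity, principal coordinates analysis and ANOSIM.

.check_distance <- function(d, tol = 1e-12) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > tol) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > tol)) stop("distance matrix must have a zero diagonal")
  if (any(d < -tol)) stop("distances must be nonnegative")
  d
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(i, j) = sum |x_ik - x_jk| / sum (x_ik + x_jk) over taxa k, computed
#' on counts or relative abundances (the statistic is scale-invariant
#' within a sample).
#'
#' @param x numeric matrix, taxa x samples, positive column totals.
#' @return symmetric sample x sample matrix with zero diagonal, entries
#'   in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  .check_counts(x)
  if (ncol(x) < 2) stop("need at least 2 samples")
  if (any(colSums(x) == 0))
    stop("Bray-Curtis is undefined for zero-total samples")
  as.matrix(vegan::vegdist(t(x), method = "bray"))
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues; the proportion explained divides each positive
#' eigenvalue by the sum of positive eigenvalues. Negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' retained in `eigenvalues` but excluded from coordinates and
#' proportions; no Cailliez correction is applied.
#'
#' @param d symmetric distance matrix with sample names.
#' @return object of class `micronet_pcoa`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, decreasing),
#'   `proportion_explained` (per retained axis) and
#'   `negative_eigenvalues` (logical).
#' @export
pcoa_ord <- function(d) {
  d <- .check_distance(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  b <- a - outer(rm, rm, "+") + mean(a)  # row/col centering; rowMeans == colMeans
  eig <- eigen(b, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- eig$values > tol
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), nrow = sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig$values,
    proportion_explained = eig$values[pos] / sum(eig$values[pos]),
    negative_eigenvalues = any(eig$values < -tol)
  ), class = "micronet_pcoa")
}

#' @export
print.micronet_pcoa <- function(x, ...) {
  cat("Principal coordinates analysis\n")
  cat(sprintf("  %d samples, %d retained axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  pe <- round(100 * x$proportion_explained[seq_len(min(3, ncol(x$coordinates)))], 2)
  cat("  variance explained (%):", paste(pe, collapse = ", "), "...\n")
  if (x$negative_eigenvalues)
    cat("  note: negative eigenvalues present (non-Euclidean input)\n")
  invisible(x)
}

.align_groups <- function(groups, ids) {
  if (!is.null(names(groups))) {
    if (!all(ids %in% names(groups)))
      stop("`groups` is missing labels for some samples")
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stop("`groups` must have one label per sample")
  }
  factor(groups)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. All pairwise distances are ranked
#' with average ranks for ties and
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4),
#' so R = 1 when every between-group distance exceeds every within-group
#' distance. The p-value uses the +1 convention,
#' p = (1 + #\{permuted R >= observed R\}) / (1 + n_perm), and so is never 0.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed.
#' @return object of class `anosim_result`: list with `statistic`,
#'   `p_value`, `n_permutations`, `permuted` (the permuted statistics).
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- .check_distance(d)
  g <- .align_groups(groups, rownames(d))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group must contain at least 2 samples")
  n <- nrow(d)
  lt <- lower.tri(d)
  r <- rank(d[lt])  # average ranks for ties
  denom <- n * (n - 1) / 4
  stat <- function(gg) {
    same <- outer(gg, gg, "==")[lt]
    (mean(r[!same]) - mean(r[same])) / denom
  }
  obs <- stat(g)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(g)), numeric(1))
  structure(list(
    statistic = obs,
    p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
    n_permutations = n_perm,
    permuted = perm
  ), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}
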