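# Linking network modules and functional guilds to environmental
# factors: module-environment correlation, per-taxon enrichment calls
# (Manhattan-plot input) and (partial) Mantel tests.

#' Module-environment Pearson correlation table
#'
#' Correlates per-sample module relative abundances with each
#' environmental factor over their shared samples, reporting Pearson r,
#' the two-sided p-value and significance stars (`*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001; boundary values get the weaker star).
#'
#' @param module_ab modules x samples abundance matrix from
#'   [module_abundance()].
#' @param env samples x factors numeric matrix or data frame.
#' @return data frame with columns `module`, `factor`, `r`, `p`, `stars`.
#' @export
module_env_correlation <- function(module_ab, env) {
  env <- as.matrix(env)
  if (!is.numeric(env)) stop("`env` must be numeric")
  shared <- intersect(colnames(module_ab), rownames(env))
  if (length(shared) < 3)
    stop("need at least 3 samples shared between module abundances and `env`")
  m <- module_ab[, shared, drop = FALSE]
  e <- env[shared, , drop = FALSE]
  grid <- expand.grid(module = rownames(m), factor = colnames(e),
                      stringsAsFactors = FALSE)
  res <- mapply(function(mod, fac) {
    ct <- suppressWarnings(cor.test(m[mod, ], e[, fac], method = "pearson"))
    c(r = unname(ct$estimate), p = ct$p.value)
  }, grid$module, grid$factor)
  grid$r <- res["r", ]
  grid$p <- res["p", ]
  grid$stars <- significance_stars(grid$p)
  rownames(grid) <- NULL
  grid
}

#' Pick the module most positively associated with the environment
#'
#' Convenience selector over a [module_env_correlation()] table: the
#' module with the largest sum of significant positive correlations
#' (falling back to the largest single r when nothing is significant).
#'
#' @param mec data frame from [module_env_correlation()].
#' @param alpha significance level used for the selection (default 0.05).
#' @return module name (character scalar).
#' @export
focal_module <- function(mec, alpha = 0.05) {
  sig <- mec$p < alpha & mec$r > 0
  score <- tapply(ifelse(sig, mec$r, 0), mec$module, sum)
  if (all(score == 0)) score <- tapply(mec$r, mec$module, max)
  names(score)[which.max(score)]
}

#' Per-taxon enrichment and depletion calls between two treatments
#'
#' Welch's t-test on log-transformed relative abundances (a
#' pseudo-fraction — half the smallest nonzero relative abundance in the
#' tested submatrix — is added before the log to admit zeros), with
#' Benjamini-Hochberg adjustment across the tested taxa. A taxon is
#' `enriched` when significantly more abundant in `group_a` than in
#' `group_b`, `depleted` in the opposite case, `ns` otherwise. The output
#' carries -log10(p) and the phylum for Manhattan plotting.
#'
#' @param rel relative-abundance matrix, taxa x samples.
#' @param taxa taxa to test (e.g. one module's members); defaults to all
#'   rows.
#' @param group_a,group_b sample identifier vectors (>= 2 samples each);
#'   `group_a` is the focal treatment whose gains are called `enriched`.
#' @param alpha FDR level for the calls (default 0.05).
#' @param pseudo pseudo-fraction; default half the smallest nonzero
#'   relative abundance among the tested values.
#' @param taxonomy optional taxonomy data frame supplying a `phylum`
#'   column.
#' @param module optional module label recorded per taxon.
#' @return data frame of class `differential_result`: columns `taxon`,
#'   `mean_a`, `mean_b`, `p`, `q`, `neg_log10_p`, `status`, `module`,
#'   `phylum`.
#' @export
differential_otus <- function(rel, taxa = rownames(rel), group_a, group_b,
                              alpha = 0.05, pseudo = NULL, taxonomy = NULL,
                              module = NA_character_) {
  .check_counts(rel)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  bad <- setdiff(c(group_a, group_b), colnames(rel))
  if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
  if (length(intersect(group_a, group_b)))
    stop("`group_a` and `group_b` must be disjoint")
  sub <- rel[taxa, c(group_a, group_b), drop = FALSE]
  if (is.null(pseudo)) {
    pos <- sub[sub > 0]
    if (!length(pos)) stop("all tested abundances are zero")
    pseudo <- min(pos) / 2
  }
  lg <- log(sub + pseudo)
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  p <- vapply(seq_len(nrow(lg)), function(i) {
    a <- lg[i, ia]; b <- lg[i, ib]
    tryCatch(t.test(a, b)$p.value,
             error = function(e) if (mean(a) == mean(b)) 1 else 0)
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  mean_a <- rowMeans(sub[, ia, drop = FALSE])
  mean_b <- rowMeans(sub[, ib, drop = FALSE])
  status <- rep("ns", length(p))
  status[q <= alpha & mean_a > mean_b] <- "enriched"
  status[q <= alpha & mean_a < mean_b] <- "depleted"
  phylum <- NA_character_
  if (!is.null(taxonomy) && "phylum" %in% colnames(taxonomy))
    phylum <- as.character(taxonomy[taxa, "phylum"])
  out <- data.frame(taxon = taxa, mean_a = mean_a, mean_b = mean_b,
                    p = p, q = q, neg_log10_p = -log10(pmax(p, 1e-300)),
                    status = status, module = module, phylum = phylum,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("differential_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "pseudo") <- pseudo
  out
}

# map the lower triangle of a permuted distance matrix: inner products
# against the (centered) reference vector give the permuted correlations
.perm_cor <- function(d2, pairs, centered_ref, denom_ref, n_perm) {
  vapply(seq_len(n_perm), function(k) {
    p <- sample(nrow(d2))
    v <- d2[cbind(p[pairs[, 1]], p[pairs[, 2]])]
    sum((v - mean(v)) * centered_ref) / denom_ref
  }, numeric(1))
}

.check_matched <- function(d1, d2) {
  if (!identical(dim(d1), dim(d2))) stop("distance matrices must match")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("distance matrices cover different samples")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  d2
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorised off-diagonal entries; the
#' permutation p-value jointly permutes rows and columns of `d2`,
#' p = (1 + #\{permuted r >= observed\}) / (1 + n_perm).
#'
#' @param d1,d2 symmetric distance matrices over the same samples
#'   (n >= 4).
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @return object of class `mantel_result`: `r`, `p_value`,
#'   `n_permutations`, `conditioned_on` (`NA` for the simple test).
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL) {
  d1 <- .check_distance(d1)
  d2 <- .check_distance(d2)
  d2 <- .check_matched(d1, d2)
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 samples")
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  v2 <- d2[lt]
  if (sd(v1) == 0 || sd(v2) == 0) stop("constant distance matrix")
  obs <- cor(v1, v2)
  if (!is.null(seed)) set.seed(seed)
  pairs <- which(lt, arr.ind = TRUE)
  c1 <- v1 - mean(v1)
  denom <- sqrt(sum(c1^2) * sum((v2 - mean(v2))^2))
  perm <- .perm_cor(d2, pairs, c1, denom, n_perm)
  structure(list(r = obs,
                 p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
                 n_permutations = n_perm, conditioned_on = NA_character_),
            class = "mantel_result")
}

#' Partial Mantel test controlling a third distance matrix
#'
#' Partial Pearson correlation of the vectorised entries of `d1` and
#' `d2` given `d_cond` (equivalently, the correlation of their residuals
#' after regressing each on `d_cond`). Permutations jointly permute rows
#' and columns of `d2` and recompute the partial statistic.
#'
#' @param d1,d2,d_cond symmetric distance matrices over the same samples.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @param label label recorded in `conditioned_on`.
#' @return object of class `mantel_result`.
#' @export
partial_mantel_test <- function(d1, d2, d_cond, n_perm = 9999, seed = NULL,
                                label = "conditioning matrix") {
  d1 <- .check_distance(d1)
  d2 <- .check_distance(d2)
  d_cond <- .check_distance(d_cond)
  d2 <- .check_matched(d1, d2)
  d_cond <- .check_matched(d1, d_cond)
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 samples")
  lt <- lower.tri(d1)
  v1 <- d1[lt]; v2 <- d2[lt]; vc <- d_cond[lt]
  if (sd(v1) == 0 || sd(v2) == 0) stop("constant distance matrix")
  partial_r <- function(r12, r1c, r2c) {
    den <- sqrt(max((1 - r1c^2) * (1 - r2c^2), 0))
    # a conditioning matrix collinear with an argument leaves no residual
    # variation: the partial correlation is 0 by convention
    if (den < 1e-12) return(0)
    (r12 - r1c * r2c) / den
  }
  cond_const <- sd(vc) == 0
  r1c <- if (cond_const) 0 else cor(v1, vc)
  obs <- if (cond_const) cor(v1, v2)
         else partial_r(cor(v1, v2), r1c, cor(v2, vc))
  if (!is.null(seed)) set.seed(seed)
  pairs <- which(lt, arr.ind = TRUE)
  perm <- vapply(seq_len(n_perm), function(k) {
    p <- sample(n)
    vp <- d2[cbind(p[pairs[, 1]], p[pairs[, 2]])]
    if (cond_const) cor(v1, vp)
    else partial_r(cor(v1, vp), r1c, cor(vp, vc))
  }, numeric(1))
  structure(list(r = obs,
                 p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
                 n_permutations = n_perm, conditioned_on = label),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  kind <- if (is.na(x$conditioned_on)) "Mantel"
          else paste0("Partial Mantel (| ", x$conditioned_on, ")")
  cat(sprintf("%s: r = %.3f, p = %.4g (%d permutations)\n",
              kind, x$r, x$p_value, x$n_permutations))
  invisible(x)
}

#' Bray-Curtis distances of a functional guild's sub-community
#'
#' Restricts the count table to taxa whose genus belongs to the named
#' guild (per the supplied genus-to-guild map) and computes Bray-Curtis
#' distances on that sub-community. Samples in which the guild is
#' entirely absent are dropped with a warning.
#'
#' @param counts count or relative-abundance matrix, taxa x samples.
#' @param taxonomy taxonomy data frame with a `genus` column.
#' @param guild_map data frame with columns `genus` and `guild`.
#' @param guild guild name, e.g. `"nitrifier"`.
#' @return symmetric distance matrix over the retained samples.
#' @export
guild_distances <- function(counts, taxonomy, guild_map, guild) {
  .check_counts(counts)
  .check_taxonomy(taxonomy)
  if (!all(c("genus", "guild") %in% colnames(guild_map)))
    stop("`guild_map` needs `genus` and `guild` columns")
  genera <- guild_map$genus[guild_map$guild == guild]
  if (!length(genera)) stop("unknown guild: ", guild)
  taxa <- rownames(counts)[as.character(taxonomy[rownames(counts), "genus"]) %in% genera]
  if (!length(taxa)) stop("guild `", guild, "` is absent from the data")
  sub <- counts[taxa, , drop = FALSE]
  empty <- colSums(sub) == 0
  if (any(empty)) {
    warning("dropping samples where the guild is absent: ",
            paste(colnames(sub)[empty], collapse = ", "))
    sub <- sub[, !empty, drop = FALSE]
  }
  bray_curtis(sub)
}

#' Euclidean distance on a single standardized environmental factor
#'
#' The factor is z-scored (population standard deviation, so that two
#' samples one full range apart keep an interpretable distance) and
#' pairwise absolute differences are returned; a constant factor yields
#' all-zero distances and standardization makes the result scale
#' invariant.
#'
#' @param env samples x factors matrix or data frame.
#' @param factor_name column to use.
#' @return symmetric distance matrix over the non-missing samples.
#' @export
env_factor_distance <- function(env, factor_name) {
  env <- as.matrix(env)
  if (!factor_name %in% colnames(env))
    stop("unknown factor: ", factor_name)
  v <- env[, factor_name]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 non-missing samples")
  s <- sqrt(mean((v - mean(v))^2))
  z <- if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  d <- abs(outer(z, z, "-"))
  dimnames(d) <- list(names(v), names(v))
  d
}
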