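# Spearman co-occurrence network inference: correlation + FDR, the
# random-matrix-theory threshold scan, network construction, module
# detection and summaries.

#' Pairwise Spearman correlation with FDR-adjusted p-values
#'
#' Computes all pairwise Spearman rank correlations between taxa across
#' samples (average ranks for ties), two-sided p-values from the
#' t-approximation t = rho * sqrt((n-2)/(1-rho^2)), and adjusted q-values
#' over the lower triangle. Constant taxa have undefined correlations;
#' their pairs are recorded as missing and excluded from any network
#' built from the result.
#'
#' @param rel numeric matrix, taxa x samples (relative abundances);
#'   >= 2 taxa and >= 4 samples.
#' @param fdr_method multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"BH"`, Benjamini-Hochberg step-up).
#' @return object of class `correlation_result`: list with `rho`, `p`,
#'   `q` (symmetric taxon x taxon matrices), `n_samples`,
#'   `constant_taxa`.
#' @export
spearman_matrix <- function(rel, fdr_method = "BH") {
  .check_counts(rel)
  n <- ncol(rel)
  if (n < 4) stop("need at least 4 samples")
  if (nrow(rel) < 2) stop("need at least 2 taxa")
  x <- t(rel)
  const <- apply(x, 2, function(v) max(v) == min(v))
  rho <- suppressWarnings(cor(x, method = "spearman"))
  if (any(const)) {
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- 1
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0  # perfect correlation: t -> Inf
  p[is.na(rho)] <- NA_real_
  diag(p) <- NA_real_
  q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  lt <- lower.tri(p)
  ok <- lt & !is.na(p)
  q[ok] <- p.adjust(p[ok], method = fdr_method)
  q[upper.tri(q)] <- t(q)[upper.tri(q)]
  structure(list(taxa = rownames(rel), rho = rho, p = p, q = q,
                 n_samples = n, fdr_method = fdr_method,
                 constant_taxa = rownames(rel)[const]),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman correlation over %d taxa, %d samples (FDR: %s)\n",
              length(x$taxa), x$n_samples, x$fdr_method))
  if (length(x$constant_taxa))
    cat("  constant taxa (correlations undefined):",
        paste(x$constant_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Adjust p-values for multiple testing and flag significance
#'
#' Thin wrapper around [stats::p.adjust()] (Benjamini-Hochberg step-up by
#' default) returning the adjusted values together with the significance
#' mask at `q_cut`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs propagate).
#' @param method adjustment method (see [stats::p.adjust.methods]).
#' @param q_cut significance cutoff on the adjusted values (default
#'   0.001, a stringent cutoff for correlation-edge screening).
#' @return list with `q` (adjusted values) and `significant` (logical).
#' @export
fdr_adjust <- function(p, method = "BH", q_cut = 0.001) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = method)
  list(q = q, significant = !is.na(q) & q <= q_cut)
}

#' Chi-square test of the eigenvalue spacing distribution against the
#' Poisson law
#'
#' Unfolds a sorted eigenvalue spectrum by fitting a smoothing polynomial
#' (default degree 5) to the empirical cumulative spectral distribution,
#' forms the nearest-neighbour spacing distribution (NNSD) of the
#' unfolded levels, and tests its fit to the Poisson law exp(-s) by a
#' chi-square test over equal-probability bins (ceiling(sqrt(m)) bins by
#' default). Uncorrelated (modular) spectra follow the Poisson law;
#' strongly mixed random spectra follow Wigner-Dyson statistics and fail
#' the test — the transition that random-matrix thresholding exploits.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @param degree polynomial degree for the spectral unfolding.
#' @param bins number of chi-square bins; default ceiling(sqrt(m)) for m
#'   spacings.
#' @return list with `statistic`, `df`, `p_value`, `n_spacings`,
#'   `spacings`; `p_value` is `NA` when the spectrum is too small or too
#'   degenerate to unfold.
#' @export
nnsd_poisson_test <- function(eigenvalues, degree = 5, bins = NULL) {
  ev <- sort(eigenvalues)
  m <- length(ev)
  failed <- list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                 n_spacings = 0L, spacings = numeric(0))
  if (m < 10 || length(unique(ev)) <= degree + 1) return(failed)
  emp <- (seq_len(m) - 0.5) / m
  fit <- tryCatch(lm(emp ~ poly(ev, degree)), error = function(e) NULL)
  if (is.null(fit)) return(failed)
  unfolded <- m * cummax(predict(fit))  # enforce a monotone unfolding
  s <- diff(unfolded)
  s <- s[is.finite(s)]
  if (length(s) < 8 || mean(s) <= 0) return(failed)
  s <- s / mean(s)
  nb <- bins %||% ceiling(sqrt(length(s)))
  edges <- qexp(seq(0, 1, length.out = nb + 1))
  obs <- tabulate(findInterval(s, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = nb)
  expected <- length(s) / nb
  stat <- sum((obs - expected)^2 / expected)
  list(statistic = stat, df = nb - 1L,
       p_value = pchisq(stat, df = nb - 1, lower.tail = FALSE),
       n_spacings = length(s), spacings = s)
}

#' Random-matrix-theory threshold scan for a correlation matrix
#'
#' For each candidate threshold the correlation matrix is hard-thresholded
#' (entries with |rho| below the candidate set to zero, unit diagonal
#' kept), restricted to taxa retaining at least one connection, and its
#' eigenvalue nearest-neighbour spacing distribution is tested against
#' the Poisson law with [nnsd_poisson_test()]. The selected threshold is
#' the smallest candidate whose NNSD is Poisson-consistent (chi-square
#' p > `p_cut`), i.e. the point where random inter-module mixing has been
#' pruned away and only modular structure remains.
#'
#' @param corr a `correlation_result` from [spearman_matrix()] or a plain
#'   symmetric correlation matrix; missing entries are treated as 0.
#' @param grid ascending candidate thresholds in (0, 1).
#' @param degree unfolding polynomial degree (see [nnsd_poisson_test()]).
#' @param p_cut chi-square p-value above which the NNSD is declared
#'   Poisson-consistent (default 0.05).
#' @param min_dim smallest thresholded matrix dimension worth testing
#'   (default 10); smaller candidates are skipped.
#' @return list of class `rmt_scan`: `threshold` (selected),
#'   `diagnostics` (data frame with one row per candidate: threshold,
#'   retained dimension, chi-square statistic, df, p-value,
#'   poisson-consistency flag).
#' @export
rmt_threshold <- function(corr, grid = seq(0.30, 0.95, by = 0.01),
                          degree = 5, p_cut = 0.05, min_dim = 10) {
  rho <- if (inherits(corr, "correlation_result")) corr$rho else as.matrix(corr)
  if (nrow(rho) != ncol(rho)) stop("correlation matrix must be square")
  if (any(grid <= 0 | grid >= 1)) stop("`grid` must lie within (0, 1)")
  if (is.unsorted(grid, strictly = TRUE)) stop("`grid` must be ascending")
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  rows <- lapply(grid, function(t) {
    a <- rho
    a[abs(a) < t] <- 0
    diag(a) <- 1
    keep <- rowSums(a != 0) > 1  # taxa retaining at least one connection
    n_keep <- sum(keep)
    if (n_keep < min_dim)
      return(data.frame(threshold = t, dim = n_keep, statistic = NA_real_,
                        df = NA_integer_, p_value = NA_real_,
                        poisson = NA))
    ev <- eigen(a[keep, keep], symmetric = TRUE, only.values = TRUE)$values
    fit <- nnsd_poisson_test(ev, degree = degree)
    data.frame(threshold = t, dim = n_keep, statistic = fit$statistic,
               df = fit$df, p_value = fit$p_value,
               poisson = !is.na(fit$p_value) && fit$p_value > p_cut)
  })
  rows <- do.call(rbind, rows)
  hit <- which(!is.na(rows$poisson) & rows$poisson)
  if (!length(hit))
    stop("no candidate threshold gave a Poisson-consistent spacing ",
         "distribution; extend or refine `grid` (the spectrum may be too ",
         "small or degenerate to show a transition)")
  structure(list(threshold = grid[hit[1]], diagnostics = rows,
                 p_cut = p_cut), class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat(sprintf("RMT threshold scan: selected |rho| >= %.2f\n", x$threshold))
  cat(sprintf("  %d candidates evaluated; Poisson consistency at chi-square p > %.2f\n",
              nrow(x$diagnostics), x$p_cut))
  invisible(x)
}

#' Build a signed co-occurrence network from thresholded correlations
#'
#' Keeps an edge between two taxa when |rho| >= `threshold` and the
#' FDR-adjusted q-value is at most `q_cut`; the correlation sign is
#' retained as an edge attribute. Isolated taxa stay in the node table,
#' flagged, so that node sets remain comparable across networks.
#'
#' @param corr `correlation_result` from [spearman_matrix()].
#' @param threshold correlation-magnitude cutoff in (0, 1), e.g. the
#'   value selected by [rmt_threshold()].
#' @param q_cut FDR cutoff for edges (default 0.001).
#' @param node_abundance optional named vector of mean relative
#'   abundances, stored as a node attribute.
#' @return object of class `cooccurrence_network`: list with `nodes`
#'   (data frame: taxon, abundance, degree, isolated), `edges` (data
#'   frame: from, to, rho, sign, q), `threshold`, `q_cut`.
#' @export
build_network <- function(corr, threshold, q_cut = 0.001,
                          node_abundance = NULL) {
  if (!inherits(corr, "correlation_result"))
    stop("`corr` must be a correlation_result from spearman_matrix()")
  if (length(threshold) != 1 || threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a fraction in (0, 1)")
  rho <- corr$rho
  q <- corr$q
  lt <- lower.tri(rho)
  keep <- lt & !is.na(rho) & !is.na(q) & abs(rho) >= threshold & q <= q_cut
  idx <- which(keep, arr.ind = TRUE)
  taxa <- corr$taxa
  edges <- data.frame(
    from = taxa[pmin(idx[, 1], idx[, 2])],
    to = taxa[pmax(idx[, 1], idx[, 2])],
    rho = rho[keep],
    sign = ifelse(rho[keep] > 0, "positive", "negative"),
    q = q[keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  degree <- setNames(numeric(length(taxa)), taxa)
  tab <- table(c(edges$from, edges$to))
  degree[names(tab)] <- as.numeric(tab)
  ab <- rep(NA_real_, length(taxa))
  if (!is.null(node_abundance)) ab <- unname(node_abundance[taxa])
  nodes <- data.frame(taxon = taxa, abundance = ab, degree = unname(degree),
                      isolated = unname(degree) == 0,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 q_cut = q_cut), class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes (%d isolated), %d edges (%d +, %d -)\n",
              nrow(x$nodes), sum(x$nodes$isolated), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  cat(sprintf("  |rho| >= %.2f, q <= %g\n", x$threshold, x$q_cut))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' Non-isolated nodes become vertices (with abundance and degree
#' attributes); edges carry `rho`, `sign`, `q` and `weight` = |rho|.
#'
#' @param net a `cooccurrence_network`.
#' @param keep_isolated include isolated nodes as degree-zero vertices.
#' @return an igraph object.
#' @export
as_igraph <- function(net, keep_isolated = FALSE) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nodes <- net$nodes
  if (!keep_isolated) nodes <- nodes[!nodes$isolated, , drop = FALSE]
  edges <- net$edges
  edges$weight <- abs(edges$rho)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = nodes[, c("taxon", "abundance", "degree")])
}

#' Detect ecological modules by modularity maximisation
#'
#' Runs seeded Louvain community detection on the |rho|-weighted network
#' and reports the partition of non-isolated nodes with its modularity Q.
#' Modules are ranked by node count (ties broken by the smallest member
#' identifier) and named `Mod 1` ... `Mod k`.
#'
#' @param net a `cooccurrence_network` with at least one edge.
#' @param seed integer seed for the (stochastic) Louvain sweep.
#' @return object of class `module_partition`: list with `module_of`
#'   (named integer vector, taxon -> module id), `module_names`,
#'   `modularity`, `sizes`, `n_modules`.
#' @export
detect_modules <- function(net, seed = 1) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (nrow(net$edges) == 0) stop("cannot detect modules in an edgeless network")
  g <- as_igraph(net)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  # rank modules by size, ties by smallest member identifier
  members <- split(names(memb), memb)
  sizes <- lengths(members)
  ord <- order(-sizes, vapply(members, function(m) min(m), character(1)))
  relabel <- setNames(seq_along(ord), names(members)[ord])
  module_of <- setNames(as.integer(relabel[as.character(memb)]), names(memb))
  q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  structure(list(
    module_of = module_of,
    module_names = paste("Mod", seq_along(ord)),
    modularity = q,
    sizes = as.integer(sort(sizes, decreasing = TRUE)),
    n_modules = length(ord)
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules over %d taxa, Q = %.3f\n",
              x$n_modules, length(x$module_of), x$modularity))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample relative abundance of network modules
#'
#' For every sample, a module's abundance is the sum of the relative
#' abundances of its member taxa; per sample the module values sum to at
#' most 1.
#'
#' @param partition a `module_partition`.
#' @param rel relative-abundance matrix whose rows include every
#'   partitioned taxon.
#' @return matrix, modules x samples, rownames `Mod 1` ... `Mod k`.
#' @export
module_abundance <- function(partition, rel) {
  stopifnot(inherits(partition, "module_partition"))
  .check_counts(rel)
  taxa <- names(partition$module_of)
  missing <- setdiff(taxa, rownames(rel))
  if (length(missing))
    stop("partition taxa absent from the abundance table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  out <- rowsum(rel[taxa, , drop = FALSE], partition$module_of[taxa])
  rownames(out) <- partition$module_names[as.integer(rownames(out))]
  out
}

#' Summary statistics of a co-occurrence network
#'
#' Node, edge, and signed-edge counts, mean degree and (when a partition
#' is given) module count and modularity — the quantities contrasted
#' between fertilisation-treatment networks.
#'
#' @param net a `cooccurrence_network`.
#' @param partition optional `module_partition`.
#' @return one-row data frame.
#' @export
network_stats <- function(net, partition = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  data.frame(
    n_nodes = nrow(net$nodes),
    n_isolated = sum(net$nodes$isolated),
    n_edges = nrow(net$edges),
    n_positive = sum(net$edges$sign == "positive"),
    n_negative = sum(net$edges$sign == "negative"),
    mean_degree = mean(net$nodes$degree),
    n_modules = if (is.null(partition)) NA_integer_ else partition$n_modules,
    modularity = if (is.null(partition)) NA_real_ else partition$modularity
  )
}
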