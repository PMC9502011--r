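# Count-table processing: rarefaction, coverage, relative abundance,
# taxonomic aggregation and the mean-abundance filter that defines the
# node set of the co-occurrence network.

.check_counts <- function(counts, integer_only = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (taxa in rows, samples in columns)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("taxon and sample identifiers must be unique")
  if (any(counts < 0)) stop("`counts` must be nonnegative")
  if (integer_only && any(counts != round(counts)))
    stop("`counts` must contain integer counts")
  invisible(counts)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples whose total is below
#' `depth` are dropped with a warning rather than scaled, which keeps the
#' table integer-valued for downstream rank-based statistics.
#'
#' @param counts integer matrix, taxa x samples.
#' @param depth target reads per sample (default 20000, the usual even
#'   depth for soil 16S libraries).
#' @param seed optional integer seed for the subsampling.
#' @return rarefied count matrix; every column sums to exactly `depth`.
#'   Samples below `depth` are absent.
#' @export
rarefy_counts <- function(counts, depth = 20000, seed = NULL) {
  .check_counts(counts, integer_only = TRUE)
  if (length(depth) != 1 || depth <= 0 || depth != round(depth))
    stop("`depth` must be a single positive integer")
  totals <- colSums(counts)
  low <- totals < depth
  if (any(low))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(low), depth,
                    paste(colnames(counts)[low], collapse = ", ")))
  counts <- counts[, !low, drop = FALSE]
  if (ncol(counts) == 0) return(counts)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(counts) == 1) {
    # single taxon: every read belongs to it
    out <- matrix(as.integer(depth), 1, ncol(counts))
  } else {
    # muffle vegan's "are these really counts?" heuristic, which fires
    # whenever the smallest nonzero count exceeds 1
    out <- withCallingHandlers(
      t(vegan::rrarefy(t(counts), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  out
}

#' Good's coverage per sample
#'
#' Estimated fraction of each sample's community captured by sequencing:
#' 1 - F1/N, where F1 is the number of taxa observed exactly once and N
#' the sample total.
#'
#' @param counts integer matrix, taxa x samples.
#' @return named numeric vector in \[0, 1\], one value per sample.
#' @export
goods_coverage <- function(counts) {
  .check_counts(counts, integer_only = TRUE)
  totals <- colSums(counts)
  if (any(totals == 0)) stop("Good's coverage is undefined for empty samples")
  1 - colSums(counts == 1) / totals
}

#' Convert counts to relative abundances
#'
#' @param counts numeric matrix, taxa x samples, with positive column sums.
#' @return matrix of per-sample proportions; each column sums to 1.
#' @export
relative_abundance <- function(counts) {
  .check_counts(counts)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("relative abundance is undefined for zero-total samples: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  sweep(counts, 2, totals, "/")
}

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

.check_taxonomy <- function(taxonomy) {
  if (!is.data.frame(taxonomy)) stop("`taxonomy` must be a data frame")
  if (is.null(rownames(taxonomy))) stop("`taxonomy` must have taxon rownames")
  invisible(taxonomy)
}

#' Aggregate a count table at a taxonomic rank
#'
#' Sums counts over taxa sharing a rank label; taxa unclassified at that
#' rank are pooled into an explicit `"unclassified"` bin rather than
#' dropped, so per-sample totals are conserved exactly.
#'
#' @param counts numeric matrix, taxa x samples.
#' @param taxonomy data frame with taxon rownames and columns named after
#'   ranks (`phylum` ... `genus`), as returned by [read_taxonomy()].
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return aggregated matrix with rank labels as rownames.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank = "genus") {
  .check_counts(counts)
  .check_taxonomy(taxonomy)
  if (!rank %in% setdiff(.RANKS, "domain"))
    stop("unknown rank `", rank, "`; use one of ",
         paste(setdiff(.RANKS, "domain"), collapse = ", "))
  if (!rank %in% colnames(taxonomy))
    stop("taxonomy table has no `", rank, "` column")
  missing <- setdiff(rownames(counts), rownames(taxonomy))
  if (length(missing))
    stop("taxa absent from the taxonomy table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  labels <- as.character(taxonomy[rownames(counts), rank])
  labels[is.na(labels) | labels == ""] <- "unclassified"
  out <- rowsum(counts, labels)
  out[order(rownames(out)), , drop = FALSE]
}

#' Filter taxa by mean relative abundance within treatment groups
#'
#' Keeps a taxon when its mean relative abundance exceeds `threshold`
#' within treatment groups. The default `"union"` rule keeps a taxon
#' passing in at least one group, which maximises comparability of the
#' network node set across treatments; `"intersection"` requires every
#' group, `"global"` uses the overall mean.
#'
#' @param rel relative-abundance matrix, taxa x samples.
#' @param groups treatment label per sample; either named by sample or
#'   ordered as the columns of `rel`.
#' @param threshold abundance fraction, in (0, 1); default 0.01 (the
#'   conventional 1% dominance filter).
#' @param rule `"union"` (default), `"intersection"` or `"global"`.
#' @return the subset of `rel` rows passing the filter.
#' @export
filter_mean_abundance <- function(rel, groups, threshold = 0.01,
                                  rule = c("union", "intersection", "global")) {
  .check_counts(rel)
  rule <- match.arg(rule)
  if (length(threshold) != 1 || threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a fraction in (0, 1)")
  if (!is.null(names(groups))) {
    if (!all(colnames(rel) %in% names(groups)))
      stop("`groups` is missing labels for some samples")
    groups <- groups[colnames(rel)]
  } else if (length(groups) != ncol(rel)) {
    stop("`groups` must have one label per sample")
  }
  g <- factor(groups)
  if (any(table(g) == 0)) stop("empty treatment group")
  means <- vapply(levels(g), function(lv)
    rowMeans(rel[, g == lv, drop = FALSE]), numeric(nrow(rel)))
  keep <- switch(rule,
    union        = apply(means > threshold, 1, any),
    intersection = apply(means > threshold, 1, all),
    global       = rowMeans(rel) > threshold)
  rel[keep, , drop = FALSE]
}
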