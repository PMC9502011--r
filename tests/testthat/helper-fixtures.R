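# Shared fixtures, built in code.

toy_counts <- function() {
  m <- matrix(c(5, 3, 1, 1,
                2, 0, 6, 2,
                0, 4, 4, 2), nrow = 4,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  storage.mode(m) <- "integer"
  m
}

toy_taxonomy <- function(taxa = paste0("t", 1:4)) {
  data.frame(domain = "Bacteria",
             phylum = c("Proteobacteria", "Proteobacteria",
                        "Actinobacteriota", "Actinobacteriota"),
             genus = c("Sphingomonas", "Sphingomonas", "Gaiella", NA),
             row.names = taxa, stringsAsFactors = FALSE)
}

# distance matrix from a coordinate matrix (samples in rows)
dist_from_points <- function(x, ids = paste0("s", seq_len(nrow(x)))) {
  d <- as.matrix(dist(x))
  dimnames(d) <- list(ids, ids)
  d
}

random_distance <- function(n, ids = paste0("s", seq_len(n))) {
  x <- matrix(rnorm(n * 3), n)
  dist_from_points(x, ids)
}

# small but structurally faithful simulation for fast tests
small_config <- function(seed = 1, ...) {
  args <- list(n_taxa = 60, depth = 2000, seed = seed)
  do.call(simulation_config, modifyList(args, list(...)))
}

# hand-built network object for module/statistics tests
manual_network <- function(edges, taxa = NULL, threshold = 0.5) {
  taxa <- taxa %||% sort(unique(c(edges$from, edges$to)))
  deg <- setNames(numeric(length(taxa)), taxa)
  tab <- table(c(edges$from, edges$to))
  deg[names(tab)] <- tab
  structure(list(
    nodes = data.frame(taxon = taxa, abundance = NA_real_,
                       degree = unname(deg), isolated = unname(deg) == 0,
                       stringsAsFactors = FALSE),
    edges = edges, threshold = threshold, q_cut = 0.001),
    class = "cooccurrence_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# weighted Newman modularity computed from first principles
modularity_oracle <- function(edges, membership) {
  w <- abs(edges$rho)
  m2 <- 2 * sum(w)
  strength <- tapply(c(w, w), c(edges$from, edges$to), sum)
  within <- membership[edges$from] == membership[edges$to]
  q <- sum(w[within]) * 2 / m2
  for (mod in unique(membership)) {
    s <- sum(strength[names(membership)[membership == mod]], na.rm = TRUE)
    q <- q - (s / m2)^2
  }
  q
}

# all set partitions of a small vector (Bell number growth: keep n <= 7)
set_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  rest <- set_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(items[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(items[1]), p)
  }
  out
}
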