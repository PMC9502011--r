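test_that("Spearman matrix matches hand-ranked computation, ties included", {
  rel <- rbind(
    t1 = c(0.1, 0.2, 0.2, 0.4, 0.5),   # tie inside
    t2 = c(0.5, 0.4, 0.3, 0.2, 0.1),   # strictly decreasing
    t3 = c(0.2, 0.2, 0.2, 0.2, 0.2))   # constant
  colnames(rel) <- paste0("s", 1:5)
  res <- spearman_matrix(rel)
  # oracle: Pearson correlation of average ranks
  oracle <- cor(rank(rel["t1", ]), rank(rel["t2", ]))
  expect_equal(res$rho["t1", "t2"], oracle, tolerance = 1e-12)
  expect_equal(diag(res$rho), c(t1 = 1, t2 = 1, t3 = 1))
  expect_identical(res$constant_taxa, "t3")
  expect_true(all(is.na(res$rho["t3", c("t1", "t2")])))

  # perfectly reversed ranks give -1 with p = 0
  rev2 <- rbind(a = 1:5 / 15, b = 5:1 / 15)
  colnames(rev2) <- paste0("s", 1:5)
  res2 <- spearman_matrix(rev2)
  expect_equal(res2$rho["a", "b"], -1)
  expect_equal(res2$p["a", "b"], 0)

  # BH q-values never fall below the raw p-values
  set.seed(4)
  rel3 <- matrix(runif(60), 6, 10,
                 dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  res3 <- spearman_matrix(rel3)
  lt <- lower.tri(res3$p)
  expect_true(all(res3$q[lt] >= res3$p[lt] - 1e-12))
  expect_error(spearman_matrix(rel3[, 1:3]), "4 samples")
})

test_that("FDR adjustment reproduces the Benjamini-Hochberg step-up by hand", {
  # step-up: q_(i) = min_{j >= i} m p_(j) / j -> all equal 0.04 here
  out <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04), q_cut = 0.05)
  expect_equal(out$q, rep(0.04, 4))
  expect_true(all(out$significant))

  one <- fdr_adjust(0.03)
  expect_equal(one$q, 0.03)

  flat <- fdr_adjust(rep(1, 5), q_cut = 0.001)
  expect_equal(flat$q, rep(1, 5))
  expect_false(any(flat$significant))

  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("NNSD machinery separates Wigner from Poisson spectra", {
  set.seed(8)
  # GOE sample: level repulsion, must reject the Poisson law
  m <- 150
  a <- matrix(rnorm(m * m), m)
  goe <- (a + t(a)) / sqrt(2 * m)
  ev_goe <- eigen(goe, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(nnsd_poisson_test(ev_goe)$p_value, 0.05)

  # independent uniform levels: Poisson-consistent
  ev_pois <- sort(runif(150))
  expect_gt(nnsd_poisson_test(ev_pois)$p_value, 0.05)

  # degenerate spectrum cannot be unfolded
  expect_true(is.na(nnsd_poisson_test(rep(1, 50))$p_value))
})

test_that("RMT scan finds a threshold inside a planted block structure", {
  # empirical correlation of factor data: 6 blocks of 10, latent within
  # 0.9 / between 0.1
  set.seed(42)
  K <- 6; per <- 10; n <- 200
  block <- rep(seq_len(K), each = per)
  f <- matrix(rnorm(K * n), K, n)
  shared <- matrix(rnorm(n), K * per, n, byrow = TRUE)
  x <- sqrt(0.1) * shared + sqrt(0.8) * f[block, ] +
    sqrt(0.1) * matrix(rnorm(K * per * n), K * per, n)
  rho <- cor(t(x))
  scan <- rmt_threshold(rho, grid = seq(0.30, 0.95, by = 0.01))
  expect_gt(scan$threshold, 0.1)
  expect_lt(scan$threshold, 0.9)
  sel <- scan$diagnostics[scan$diagnostics$threshold == scan$threshold, ]
  expect_true(sel$poisson)
  expect_gt(sel$p_value, 0.05)

  # identity matrix: no spacings to test, scan must refuse
  expect_error(rmt_threshold(diag(30), grid = c(0.3, 0.5)), "extend")
  expect_error(rmt_threshold(rho, grid = c(0.5, 0.4)), "ascending")
  expect_error(rmt_threshold(rho, grid = c(0.5, 1.5)), "within")
})

test_that("network construction thresholds edges with signs and monotonicity", {
  # craft exact rank relationships: t1 ~ t2 (rho 1), t3 ~ -t4 (rho -1),
  # t5 noise
  set.seed(6)
  base <- runif(8)
  rel <- rbind(t1 = base, t2 = base^2, t3 = sort(runif(8)),
               t4 = sort(runif(8), decreasing = TRUE), t5 = runif(8))
  colnames(rel) <- paste0("s", 1:8)
  corr <- spearman_matrix(rel)
  net <- build_network(corr, threshold = 0.99, q_cut = 0.01)
  e <- net$edges
  expect_equal(nrow(e), 2)
  expect_setequal(paste(e$from, e$to), c("t1 t2", "t3 t4"))
  expect_equal(sort(e$sign), c("negative", "positive"))
  expect_true(net$nodes$isolated[net$nodes$taxon == "t5"])

  # lowering the threshold can only add edges
  loose <- build_network(corr, threshold = 0.3, q_cut = 0.05)
  key <- function(x) paste(x$edges$from, x$edges$to)
  expect_true(all(key(net) %in% key(loose)))
  # tightening q_cut can only remove edges
  strictq <- build_network(corr, threshold = 0.3, q_cut = 1e-6)
  expect_true(all(key(strictq) %in% key(loose)))

  expect_error(build_network(corr, threshold = 1), "fraction")
})

test_that("module detection recovers components and the modularity value", {
  # two disconnected triangles; all |rho| equal
  tri <- function(v) data.frame(
    from = v[c(1, 1, 2)], to = v[c(2, 3, 3)],
    rho = 0.9, sign = "positive", q = 1e-6, stringsAsFactors = FALSE)
  edges <- rbind(tri(c("a1", "a2", "a3")), tri(c("b1", "b2", "b3")))
  net <- manual_network(edges)
  part <- detect_modules(net, seed = 1)
  expect_equal(part$n_modules, 2)
  expect_length(unique(part$module_of[c("a1", "a2", "a3")]), 1)
  expect_length(unique(part$module_of[c("b1", "b2", "b3")]), 1)

  # reported Q equals the hand formula, and is the global maximum over
  # every partition of the 6 nodes
  q_hand <- modularity_oracle(edges, part$module_of)
  expect_equal(part$modularity, q_hand, tolerance = 1e-12)
  nodes <- net$nodes$taxon
  best <- max(vapply(set_partitions(nodes), function(p) {
    memb <- setNames(rep(seq_along(p), lengths(p)), unlist(p))
    modularity_oracle(edges, memb[nodes])
  }, numeric(1)))
  expect_equal(part$modularity, best, tolerance = 1e-12)

  # deterministic under a fixed seed
  expect_identical(detect_modules(net, seed = 3)$module_of,
                   detect_modules(net, seed = 3)$module_of)

  empty <- manual_network(edges[0, ], taxa = c("x", "y"))
  expect_error(detect_modules(empty), "edgeless")
})

test_that("module abundances sum member relative abundances per sample", {
  edges <- data.frame(from = c("t1", "t3"), to = c("t2", "t4"),
                      rho = c(0.9, 0.8), sign = "positive", q = 1e-6,
                      stringsAsFactors = FALSE)
  net <- manual_network(edges)
  part <- detect_modules(net, seed = 1)
  rel <- matrix(c(0.4, 0.1, 0.3, 0.2,
                  0.25, 0.25, 0.25, 0.25), ncol = 2,
                dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  ma <- module_abundance(part, rel)
  # pairs {t1,t2} and {t3,t4}; hand sums
  pair1 <- part$module_names[part$module_of["t1"]]
  expect_equal(unname(ma[pair1, ]), c(0.5, 0.5))
  expect_true(all(colSums(ma) <= 1 + 1e-12))

  # a single module holding every taxon sums to 1
  one <- structure(list(module_of = setNames(rep(1L, 4), paste0("t", 1:4)),
                        module_names = "Mod 1", modularity = 0,
                        sizes = 4L, n_modules = 1L),
                   class = "module_partition")
  expect_equal(unname(module_abundance(one, rel)[1, ]), c(1, 1))

  expect_error(module_abundance(part, rel[1:3, ]), "absent")
})

test_that("network statistics count nodes, edges and signs", {
  edges <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                      rho = c(0.9, -0.8, 0.7), sign = c("positive", "negative", "positive"),
                      q = 1e-6, stringsAsFactors = FALSE)
  net <- manual_network(edges, taxa = c("a", "b", "c", "d"))
  st <- network_stats(net)
  expect_equal(st$n_nodes, 4)
  expect_equal(st$n_edges, 3)
  expect_equal(st$n_positive, 2)
  expect_equal(st$n_negative, 1)
  expect_equal(st$n_isolated, 1)
  expect_equal(st$mean_degree, 6 / 4)

  # complete graph on n nodes has n(n-1)/2 edges
  n <- 5
  cmb <- t(combn(letters[1:n], 2))
  full <- manual_network(data.frame(from = cmb[, 1], to = cmb[, 2],
                                    rho = 0.9, sign = "positive", q = 1e-6))
  expect_equal(network_stats(full)$n_edges, n * (n - 1) / 2)

  lonely <- manual_network(edges[0, ], taxa = "z")
  expect_equal(network_stats(lonely)$mean_degree, 0)
})

test_that("network exports are well-formed and re-readable", {
  edges <- data.frame(from = c("t1", "t2"), to = c("t2", "t3"),
                      rho = c(0.9, -0.75), sign = c("positive", "negative"),
                      q = c(1e-6, 1e-4), stringsAsFactors = FALSE)
  net <- manual_network(edges)
  net$nodes$abundance <- c(0.5, 0.3, 0.2)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::edge_attr(g, "rho"), edges$rho)

  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_network_gexf(net, gexf)
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), 3)
  expect_length(xml2::xml_find_all(doc, "//d1:edge", ns), 2)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(net, csv)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(back$rho, edges$rho)
})
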