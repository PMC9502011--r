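test_that("module-environment correlation matches hand Pearson with stars", {
  ma <- rbind("Mod 1" = c(0.1, 0.2, 0.3, 0.4),
              "Mod 2" = c(0.4, 0.1, 0.3, 0.2))
  colnames(ma) <- paste0("s", 1:4)
  env <- cbind(copy = ma["Mod 1", ],       # exact copy: r = 1
               other = c(2.0, 1.5, 0.8, 1.1))
  rownames(env) <- colnames(ma)
  mec <- module_env_correlation(ma, env)
  r_copy <- mec$r[mec$module == "Mod 1" & mec$factor == "copy"]
  expect_equal(r_copy, 1, tolerance = 1e-12)
  expect_equal(mec$stars[mec$module == "Mod 1" & mec$factor == "copy"], "***")
  # hand Pearson for an arbitrary pair
  expect_equal(mec$r[mec$module == "Mod 2" & mec$factor == "other"],
               cor(ma["Mod 2", ], env[, "other"]), tolerance = 1e-12)
  expect_error(module_env_correlation(ma[, 1:2], env[1:2, ]), "3 samples")
})

test_that("significance stars use strict boundaries", {
  expect_identical(significance_stars(c(0.2, 0.05, 0.049, 0.01, 0.009,
                                        0.001, 0.0009)),
                   c("", "", "*", "*", "**", "**", "***"))
})

test_that("star rate under a null factor stays near the nominal level", {
  set.seed(31)
  hits <- replicate(200, {
    ma <- matrix(runif(12), 1, 12, dimnames = list("Mod 1", paste0("s", 1:12)))
    env <- matrix(rnorm(12), 12, 1, dimnames = list(paste0("s", 1:12), "f"))
    module_env_correlation(ma, env)$p < 0.05
  })
  rate <- mean(hits)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("differential calls flag spiked taxa with the right direction", {
  set.seed(12)
  base <- matrix(runif(8 * 6, 0.01, 0.02), 8, 6,
                 dimnames = list(paste0("t", 1:8), paste0("s", 1:6)))
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
  # identical groups: nothing is called
  sym <- base
  sym[, gb] <- sym[, ga]
  res0 <- differential_otus(sym, group_a = ga, group_b = gb)
  expect_true(all(res0$status == "ns"))

  # 10-fold spike of t1 in group_a with tiny noise
  spiked <- base
  spiked["t1", ga] <- spiked["t1", ga] * 10
  res <- differential_otus(spiked, group_a = ga, group_b = gb)
  expect_equal(res$status[res$taxon == "t1"], "enriched")
  # swapping the groups flips the direction
  swap <- differential_otus(spiked, group_a = gb, group_b = ga)
  expect_equal(swap$status[swap$taxon == "t1"], "depleted")
  expect_equal(res$p, swap$p, tolerance = 1e-12)

  # output carries Manhattan-plot columns
  expect_true(all(c("neg_log10_p", "status", "module", "phylum") %in% names(res)))
  expect_equal(res$neg_log10_p, -log10(res$p), tolerance = 1e-12)

  expect_error(differential_otus(base, group_a = ga[1], group_b = gb),
               "at least 2")
  expect_error(differential_otus(base, group_a = ga, group_b = c(ga[1], gb[1])),
               "disjoint")
})

test_that("Mantel r and p match the brute-force permutation oracle", {
  set.seed(14)
  d1 <- random_distance(5)
  d2 <- random_distance(5)
  # identity: r exactly 1, p at the permutation floor region
  self <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)

  # observed r equals the vegan statistic
  veg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 0)
  ours <- mantel_test(d1, d2, n_perm = 9999, seed = 2)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)

  # exact p by enumerating all 120 relabelings of d2
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  perms <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5, 1:5))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  rs <- apply(perms, 1, function(p) cor(v1, d2[p, p][lt]))
  p_exact <- mean(rs >= ours$r)
  expect_lt(abs(ours$p_value - p_exact), 0.02)

  # symmetry of the statistic in its arguments
  rev <- mantel_test(d2, d1, n_perm = 99, seed = 3)
  expect_equal(rev$r, ours$r, tolerance = 1e-12)

  expect_error(mantel_test(d1, random_distance(6)), "match")
})

test_that("Mantel null p-values are approximately uniform", {
  set.seed(15)
  pvals <- replicate(200,
    mantel_test(random_distance(8), random_distance(8), n_perm = 99)$p_value)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("partial Mantel equals the residual-correlation computation", {
  set.seed(16)
  d1 <- random_distance(7)
  d2 <- random_distance(7)
  dc <- random_distance(7)
  res <- partial_mantel_test(d1, d2, dc, n_perm = 99, seed = 1)
  lt <- lower.tri(d1)
  r1 <- resid(lm(d1[lt] ~ dc[lt]))
  r2 <- resid(lm(d2[lt] ~ dc[lt]))
  expect_equal(res$r, cor(r1, r2), tolerance = 1e-10)

  # conditioning on the second matrix itself drives the partial r to 0
  self <- partial_mantel_test(d1, d2, d2, n_perm = 99, seed = 1)
  expect_lt(abs(self$r), 1e-10)

  # constant conditioning matrix reduces to the simple Mantel r
  const <- matrix(1, 7, 7, dimnames = dimnames(d1)); diag(const) <- 0
  red <- partial_mantel_test(d1, d2, 0 * const, n_perm = 99, seed = 1)
  expect_equal(red$r, mantel_test(d1, d2, n_perm = 9, seed = 1)$r,
               tolerance = 1e-12)
})

test_that("guild distances restrict to the guild's genera", {
  counts <- toy_counts()
  tax <- toy_taxonomy()
  gm <- data.frame(genus = c("Sphingomonas", "Gaiella"),
                   guild = c("nitrifier", "denitrifier"))
  # guild covering all classified taxa of a genus: equals hand Bray-Curtis
  gd <- guild_distances(counts, tax, gm, "nitrifier")
  sub <- counts[c("t1", "t2"), ]
  expect_equal(gd, bray_curtis(sub))

  # a guild covering every taxon reproduces whole-community distances
  all_map <- data.frame(genus = c("Sphingomonas", "Gaiella"), guild = "all")
  tax2 <- tax
  tax2["t4", "genus"] <- "Gaiella"
  expect_equal(guild_distances(counts, tax2, all_map, "all"),
               bray_curtis(counts))

  expect_error(guild_distances(counts, tax, gm, "methanogen"), "unknown guild")
})

test_that("environmental factor distance standardizes before differencing", {
  env <- cbind(f = c(s1 = 0, s2 = 2))
  d <- env_factor_distance(env, "f")
  # population SD of (0, 2) is 1, so the z-scores are -1 and 1
  expect_equal(d["s1", "s2"], 2)

  # scale invariance
  expect_equal(env_factor_distance(10 * env, "f"), d)

  const <- cbind(f = c(s1 = 3, s2 = 3, s3 = 3))
  expect_true(all(env_factor_distance(const, "f") == 0))

  expect_error(env_factor_distance(env, "g"), "unknown factor")
})
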