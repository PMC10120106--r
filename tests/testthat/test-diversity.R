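test_that("alpha indices match hand formulas and brute-force oracles", {
  expect_equal(alpha_diversity(c(5, 5, 5, 5), "shannon"), log(4))
  expect_equal(alpha_diversity(7, "shannon"), 0)
  expect_equal(alpha_diversity(7, "simpson"), 0)
  expect_equal(alpha_diversity(c(1, 1, 2, 3), "chao1"), 4.5)
  expect_error(alpha_diversity(c(0, 0), "shannon"), "all-zero")
  set.seed(10)
  for (r in 1:25) {
    counts <- rpois(sample(2:6, 1), sample(c(2, 8, 30), 1))
    if (sum(counts) == 0) next
    expect_equal(alpha_diversity(counts, "shannon"), oracle_shannon(counts),
                 tolerance = 1e-12)
    expect_equal(alpha_diversity(counts, "simpson"), oracle_simpson(counts),
                 tolerance = 1e-12)
    expect_equal(alpha_diversity(counts, "chao1"), oracle_chao1(counts),
                 tolerance = 1e-12)
    expect_gte(alpha_diversity(counts, "chao1"),
               alpha_diversity(counts, "observed"))
  }
})

test_that("ACE and Chao1 agree with vegan's estimateR", {
  skip_if_not_installed("vegan")
  set.seed(2)
  m <- matrix(rpois(120, 2.5), 30, 4,
              dimnames = list(paste0("t", 1:30), paste0("s", 1:4)))
  m <- m + matrix(rpois(120, 15) * (runif(120) < 0.2), 30, 4)
  er <- vegan::estimateR(t(m))
  expect_equal(unname(apply(m, 2, alpha_diversity, index = "ace")),
               unname(er["S.ACE", ]), tolerance = 1e-9)
  expect_equal(unname(apply(m, 2, alpha_diversity, index = "chao1")),
               unname(er["S.chao1", ]), tolerance = 1e-9)
})

test_that("rarefaction matches the hypergeometric closed form", {
  counts <- c(4, 4, 2)
  rc <- rarefaction_curve(counts, depths = c(1, 5, 10), reps = 4000, seed = 2)
  expect_equal(rc$richness[1], 1)                      # depth 1
  expect_equal(rc$richness[3], 3)                      # depth N = S_obs exactly
  expect_equal(rc$richness[2], oracle_rarefaction(counts, 5), tolerance = 0.03)
  expect_true(all(diff(rc$richness) >= 0))
  expect_error(rarefaction_curve(counts, depths = 11), "depth")
})

test_that("Bray-Curtis matches hand computation and its metric properties", {
  m <- cbind(x = c(2, 1), y = c(1, 3))
  expect_equal(bray_curtis(m)["x", "y"], 3 / 7)
  same <- cbind(a = c(1, 2), b = c(1, 2))
  expect_equal(bray_curtis(same)["a", "b"], 0)
  disj <- cbind(a = c(5, 0), b = c(0, 3))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  set.seed(3)
  tab <- matrix(rpois(50, 10), 10, 5, dimnames = list(NULL, paste0("s", 1:5)))
  D <- bray_curtis(tab)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(D[i, j], oracle_bray(tab[, i], tab[, j]), tolerance = 1e-12)
  }
  expect_error(bray_curtis(cbind(a = c(1, 1), b = c(0, 0))), "zero total")
})

test_that("PCoA solves the two-point case and round-trips Euclidean input", {
  D0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(pcoa(D0)$points == 0) || ncol(pcoa(D0)$points) == 0)
  D2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(D2)
  expect_equal(sum(p2$eigenvalues > 1e-12), 1)
  expect_equal(unname(sort(abs(p2$points[, 1]))), c(0.5, 0.5))
  set.seed(4)
  pts <- matrix(rnorm(14), 7, 2)
  DE <- as.matrix(dist(pts)); dimnames(DE) <- list(1:7, 1:7)
  rec <- pcoa(DE)$points
  expect_lt(max(abs(as.matrix(dist(rec)) - DE)), 1e-9)
  bad <- DE; bad[1, 2] <- bad[1, 2] + 1
  expect_error(pcoa(bad), "symmetric")
})

test_that("NMDS embeds exactly embeddable data and is rotation invariant", {
  set.seed(5)
  pts <- matrix(rnorm(6), 3, 2)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(1:3, 1:3)
  res <- nmds(D, k = 2, n_starts = 5, seed = 1)
  expect_lt(res$stress, 1e-4)
  # planar points at larger n: Shepard correlation essentially 1
  pts8 <- matrix(rnorm(16), 8, 2)
  D8 <- as.matrix(dist(pts8)); dimnames(D8) <- list(1:8, 1:8)
  r8 <- nmds(D8, k = 2, n_starts = 10, seed = 2)
  d_conf <- as.vector(dist(r8$points))
  expect_gt(cor(d_conf, as.vector(as.dist(D8))), 0.99)
  # stress unchanged under rotation/reflection of the configuration
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  rot <- r8$points %*% R
  d_rot <- as.vector(dist(rot))
  expect_equal(sqrt(sum((sort(d_rot) - sort(d_conf))^2)), 0, tolerance = 1e-9)
  degenerate <- matrix(1, 4, 4) - diag(4)
  dimnames(degenerate) <- list(1:4, 1:4)
  expect_error(nmds(degenerate), "degenerate")
})

test_that("PERMANOVA agrees with the brute-force enumeration oracle", {
  set.seed(6)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(1:6, 1:6)
  groups <- rep(c("a", "b"), each = 3)
  res <- permanova(D, groups)
  expect_true(res$exhaustive)
  expect_equal(res$pseudo_F, oracle_permanova_F(D, groups), tolerance = 1e-12)
  fs <- vapply(oracle_two_group_assignments(3, 3),
               function(g) oracle_permanova_F(D, g), numeric(1))
  expect_equal(res$p, mean(fs >= res$pseudo_F - 1e-12), tolerance = 1e-12)
})

test_that("PERMANOVA pseudo-F matches vegan adonis2 and handles identical groups", {
  skip_if_not_installed("vegan")
  set.seed(7)
  tab <- matrix(rpois(60, 15), 10, 6, dimnames = list(NULL, paste0("s", 1:6)))
  D <- bray_curtis(tab)
  g <- rep(c("a", "b"), 3)
  res <- permanova(D, g, exhaustive_limit = 0, n_perm = 99, seed = 1)
  fit <- vegan::adonis2(as.dist(D) ~ g, permutations = 9)
  expect_equal(res$pseudo_F, fit$F[1], tolerance = 1e-9)
  # two groups identical point-wise: F ~ 0, p ~ 1
  m <- cbind(a1 = c(5, 1), a2 = c(1, 5), b1 = c(5, 1), b2 = c(1, 5))
  Di <- bray_curtis(m)
  ri <- permanova(Di, c("a", "a", "b", "b"))
  expect_lt(abs(ri$pseudo_F), 1e-9)
  expect_gt(ri$p, 0.6)
  expect_error(permanova(Di, c("a", "a", "a", "a")), "2 groups")
})

test_that("PERMANOVA p is invariant to relabeling samples within groups", {
  set.seed(8)
  pts <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(1:8, 1:8)
  g <- rep(c("a", "b"), each = 4)
  p1 <- permanova(D, g)$p
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7)  # swap within groups
  p2 <- permanova(D[perm, perm], g)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("Welch t and one-way ANOVA match their formula oracles and stats::", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  gt <- group_tests(c(x, y), rep(c("a", "b"), each = 4), "welch_t")
  o <- oracle_welch(x, y)
  expect_equal(gt$statistic, o$t, tolerance = 1e-12)
  expect_equal(gt$p, o$p, tolerance = 1e-12)
  tt <- t.test(x, y)
  expect_equal(gt$statistic, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(gt$p, tt$p.value, tolerance = 1e-9)
  # identical groups
  same <- group_tests(c(x, x), rep(c("a", "b"), each = 4), "welch_t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  eq <- group_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3), "anova")
  expect_equal(eq$statistic, 0)
  set.seed(9)
  vals <- rnorm(12); gg <- rep(1:3, each = 4)
  ga <- group_tests(vals, gg, "anova")
  ref <- anova(lm(vals ~ factor(gg)))
  expect_equal(ga$statistic, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(ga$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  expect_error(group_tests(c(1, 2, 3), c("a", "a", "b"), "welch_t"), ">= 2 values")
})

test_that("root/leaf Shannon difference is detected by Welch t with high power", {
  hits <- 0L
  for (s in 1:15) {
    cfg <- sim_config(seed = 100 + s, n_taxa_pool = 80, depth_per_sample = 4000)
    comm <- simulate_communities(cfg)
    h <- apply(comm$abundance, 2, alpha_diversity, index = "shannon")
    tissue <- comm$meta$tissue[match(names(h), comm$meta$sample)]
    res <- group_tests(h, tissue, "welch_t")
    if (res$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 15, 0.8)
})
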