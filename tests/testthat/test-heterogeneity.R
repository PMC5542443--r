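test_that("Weir-Cockerham F_ST: fixed disjoint alleles and label invariance", {
  g <- genotype_matrix(paste0("i", 1:20), "L1",
                       c(rep("A", 10), rep("B", 10)),
                       c(rep("A", 10), rep("B", 10)))
  f <- fst_among_pools(g, rep(1:2, each = 10), n_perm = 99, seed = 1)
  expect_equal(f$Fst, 1)
  expect_lte(f$p, 0.02)
  # category relabelling invariance
  f2 <- fst_among_pools(g, rep(c("north", "south"), each = 10),
                        n_perm = 99, seed = 1)
  expect_equal(f2$Fst, f$Fst)
  expect_equal(f2$p, f$p)
  # NA labels dropped; single usable group errors
  expect_error(fst_among_pools(g, c(rep(1, 10), rep(NA, 10))), "2 groups")
})

test_that("ANOVA on scores: F = t^2 with two groups; calibration under null", {
  set.seed(10)
  sc <- stats::rnorm(30)
  gr <- rep(c("a", "b"), 15)
  an <- anova_scores(sc, gr)
  tt <- stats::t.test(sc[gr == "a"], sc[gr == "b"], var.equal = TRUE)
  expect_equal(an$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(an$p, tt$p.value, tolerance = 1e-12)
  # groups with < 2 members are dropped with a warning
  expect_warning(anova_scores(stats::rnorm(7), c(1, 1, 1, 2, 2, 2, 3)),
                 "fewer than 2")
  # P uniform when groups are drawn from one normal
  p <- vapply(1:500, function(i) {
    set.seed(120000 + i)
    anova_scores(stats::rnorm(30), rep(1:3, 10))$p
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("Fisher association: exact 2x2, Monte-Carlo r x c, errors", {
  ft <- fisher_association(rbind(c(10, 0), c(0, 10)))
  expect_equal(ft$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(ft$p_type, "exact")

  # strong 3x2 coupling is significant under the Monte-Carlo branch
  tb <- rbind(c(12, 0), c(0, 11), c(1, 9))
  fm <- fisher_association(tb, n_mc = 1e4, seed = 3)
  expect_equal(fm$p_type, "monte_carlo")
  expect_lt(fm$p, 0.001)
  # row/column relabelling invariance (up to Monte-Carlo noise: the same
  # seed draws different tables once the margins are reordered)
  fm2 <- fisher_association(tb[c(2, 3, 1), c(2, 1)], n_mc = 1e4, seed = 3)
  expect_lt(abs(fm2$p - fm$p), 0.005)

  expect_error(fisher_association(rbind(c(0, 0), c(3, 4))), "empty margin")
  expect_error(fisher_association(matrix(1:3, 3, 1)), ">= 2 categories")
})

test_that("partial Mantel: identity, constant control, vegan oracle, cline fixture", {
  set.seed(12)
  n <- 60
  x <- stats::runif(n, 0, 100); y <- stats::runif(n, 0, 100)
  p <- x / 100
  lab_a <- ifelse(stats::runif(n) < p, "A1", "A2")
  lab_b <- ifelse(stats::runif(n) < p, "B1", "B2")
  sa <- similarity_matrix(lab_a); sb <- similarity_matrix(lab_b)
  ctrl <- as.matrix(stats::dist(cbind(x, y)))

  # sim_a == sim_b gives r = 1
  expect_equal(partial_mantel(sa, sa, ctrl, n_perm = 9, seed = 1)$statistic, 1)

  # constant control reduces exactly to the simple Mantel correlation
  simple <- partial_mantel(sa, sb, matrix(1, n, n), n_perm = 999, seed = 3)
  ut <- upper.tri(sa)
  expect_equal(simple$statistic, stats::cor(sa[ut], sb[ut]), tolerance = 1e-12)

  # vegan agreement on both the simple and partial statistic
  part <- partial_mantel(sa, sb, ctrl, n_perm = 999, seed = 3)
  vm <- vegan::mantel(stats::as.dist(sa), stats::as.dist(sb),
                      permutations = 9)
  vpm <- vegan::mantel.partial(stats::as.dist(sa), stats::as.dist(sb),
                               stats::as.dist(ctrl), permutations = 9)
  expect_equal(simple$statistic, unname(vm$statistic), tolerance = 1e-10)
  expect_equal(part$statistic, unname(vpm$statistic), tolerance = 1e-10)

  # labels coupled only through the shared spatial cline: controlling for
  # distance attenuates the association
  expect_lt(part$statistic, simple$statistic)

  expect_error(partial_mantel(matrix(1, n, n), sb, ctrl, n_perm = 9, seed = 1),
               "constant")
})

test_that("continental t-test reproduces the printed contrasts", {
  tab <- symphonia_fsgs()
  af <- tab$Sp[tab$continent == "Africa"]
  nt <- tab$Sp[tab$continent == "Neotropics"]
  tt <- continental_ttest(af, nt)
  expect_equal(round(tt$p, 3), 0.029)
  expect_equal(tt$df, 5)

  # recomputed P = 0.01349 rounds to 0.013, one last-digit unit under the
  # reported 0.014: compare at one-ulp tolerance of the printed precision
  te <- continental_ttest(tab$eig_spca[tab$continent == "Africa"],
                          tab$eig_spca[tab$continent == "Neotropics"])
  expect_equal(te$p, 0.013494, tolerance = 1e-4)
  expect_lt(abs(te$p - 0.014), 1e-3)

  t0 <- continental_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 0.5)
  expect_error(continental_ttest(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("Spearman: exact small-sample enumeration and analytic branch", {
  r1 <- spearman_exact(1:7, (1:7) * 2)
  expect_equal(r1$statistic, 1)
  expect_equal(r1$p, 1 / factorial(7))
  expect_equal(r1$p_type, "exact")

  # n = 12 uses the analytic approximation
  set.seed(5)
  x <- stats::rnorm(12); y <- x + stats::rnorm(12)
  r2 <- spearman_exact(x, y)
  expect_equal(r2$p_type, "analytic")
  expect_equal(r2$p,
               stats::cor.test(x, y, method = "spearman", exact = FALSE,
                               alternative = "greater")$p.value)
  expect_error(spearman_exact(rep(1, 5), 1:5), "constant")
})
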