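test_that("Loiselle kinship matches the brute-force oracle", {
  # small worked instance, single locus
  g <- genotype_matrix(paste0("i", 1:4), "L1",
                       c("1", "1", "2", "3"), c("2", "1", "2", "3"))
  k <- loiselle_kinship(g)
  expect_equal(k$F, loiselle_oracle(g), tolerance = 1e-12,
               ignore_attr = TRUE)
  # random multi-locus instance with missing data
  g2 <- rand_geno(12, 3, 4, seed = 8)
  g2$a1[2, 1] <- NA; g2$a2[2, 1] <- NA
  g2$a1[5, 3] <- NA; g2$a2[5, 3] <- NA
  k2 <- loiselle_kinship(g2)
  expect_equal(k2$F, loiselle_oracle(g2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("clonal copies have kinship well above the half-sib value", {
  g <- rand_geno(40, 4, 10, seed = 13)
  for (j in 1:4) { g$a1[2, j] <- g$a1[1, j]; g$a2[2, j] <- g$a2[1, j] }
  k <- loiselle_kinship(g)
  expect_gt(k$F[1, 2], 0.25)
})

test_that("mean pairwise kinship on panmictic data is a small negative value", {
  # The sample-referenced estimator with the +p(1-p)/(n_l-1) correction has
  # mean pair kinship ~ -1/(4 n^2), far smaller in magnitude than the
  # -1/(n-1) of uncorrected relatedness estimators.
  means <- vapply(1:20, function(i) {
    g <- rand_geno(30, 5, 8, seed = 300 + i)
    mean(loiselle_kinship(g)$F, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means)), 1 / (5 * 29))
  expect_lt(abs(mean(means) - (-1 / (4 * 30^2))), 5e-4)
})

test_that("distance classes: near-equal pair counts, degenerate case, diagnostics", {
  # 10 collinear equidistant points: 45 pairs, heavy distance ties, so the
  # 15/15/15 split is unattainable; quantile bounds get as close as ties allow
  s <- spatial_frame(paste0("i", 1:10), 1:10, rep(0, 10))
  sc <- build_distance_classes(s, 3)
  expect_equal(sum(sc$diagnostics$pairs), 45)
  expect_true(all(abs(sc$diagnostics$pairs - 15) <= 3))

  # all points identical: degenerate single class with rejection report
  s0 <- spatial_frame(c("a", "b", "c"), c(1, 1, 1), c(2, 2, 2))
  sc0 <- build_distance_classes(s0, 2)
  expect_false(sc0$valid)
  expect_match(sc0$report, "identical")

  # 94 individuals on a transect-like strip, 7 classes: diagnostics pass
  set.seed(5)
  st <- spatial_frame(paste0("t", 1:94), stats::runif(94, 0, 1500),
                      stats::runif(94, 0, 100))
  sct <- build_distance_classes(st, 7)
  expect_true(sct$valid)
  expect_true(all(sct$diagnostics$pct_individuals > 50))
  expect_true(all(sct$diagnostics$cv_participation < 1))
})

test_that("Sp identity holds on every correlogram output", {
  expect_equal(sp_statistic(0, 0.1), 0)
  g <- rand_geno(25, 3, 5, seed = 21)
  s <- rand_coords(g, seed = 22)
  cg <- correlogram(loiselle_kinship(g), s, n_perm = 99, seed = 23)
  expect_equal(cg$Sp, -cg$b / (1 - cg$F1), tolerance = 1e-14)
})

test_that("the slope is invariant to uniform coordinate rescaling", {
  g <- rand_geno(20, 3, 5, seed = 31)
  s <- rand_coords(g, seed = 32)
  s3 <- s; s3$x <- s$x * 7; s3$y <- s$y * 7
  class(s3) <- class(s)
  k <- loiselle_kinship(g)
  b1 <- correlogram(k, s, n_perm = 9, seed = 1)$b
  b2 <- correlogram(k, s3, n_perm = 9, seed = 1)$b
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("zero-distance pairs are excluded from the regression but counted", {
  g <- rand_geno(12, 3, 5, seed = 41)
  set.seed(42)
  x <- stats::runif(12); y <- stats::runif(12)
  x[2] <- x[1]; y[2] <- y[1]     # co-located pair (clonal ramets)
  s <- spatial_frame(g$ids, x, y)
  cg <- correlogram(loiselle_kinship(g), s, n_perm = 9, seed = 2)
  expect_equal(cg$n_zero_excluded, 1L)
  expect_true(is.finite(cg$b))
})

test_that("jackknife SE over loci is finite and flagged for few loci", {
  g <- rand_geno(20, 3, 6, seed = 51)
  s <- rand_coords(g, seed = 52)
  cg <- correlogram(loiselle_kinship(g), s, n_perm = 9, seed = 53)
  expect_true(is.finite(cg$b_se))
  expect_match(attr(cg$b_se, "note"), "fewer than 4")
})

test_that("plastid FSGS: monomorphic data declined, clustered haplotypes strong", {
  h0 <- haplotype_set(paste0("i", 1:10), rep("H1", 10))
  s0 <- spatial_frame(h0$ids, 1:10, rep(0, 10))
  expect_message(r0 <- plastid_fsgs(h0, s0, n_perm = 9, seed = 1),
                 "monomorphic")
  expect_null(r0)

  # two far-apart monomorphic patches: maximal structure
  ids <- paste0("i", 1:20)
  h <- haplotype_set(ids, rep(c("H1", "H2"), each = 10))
  set.seed(7)
  s <- spatial_frame(ids,
                     c(stats::runif(10, 0, 10), stats::runif(10, 500, 510)),
                     stats::runif(20, 0, 10))
  cg <- plastid_fsgs(h, s, n_perm = 99, seed = 3)
  # with same-haplotype kinship > 1, an all-within-patch first class pushes
  # F1 above 1 and flips the sign of Sp = -b/(1 - F1); the structure itself
  # shows as a strongly negative, significant slope and a large F1
  expect_lt(cg$b, 0)
  expect_lte(cg$p_slope, 0.02)
  expect_gt(cg$F1, 0.5)
})

test_that("correlogram reproducibility under a fixed seed", {
  g <- rand_geno(15, 3, 5, seed = 61)
  s <- rand_coords(g, seed = 62)
  k <- loiselle_kinship(g)
  c1 <- correlogram(k, s, n_perm = 49, seed = 99)
  c2 <- correlogram(k, s, n_perm = 49, seed = 99)
  expect_identical(c1, c2)
  expect_error(correlogram(k, s, n_perm = 49), "seed")
})
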