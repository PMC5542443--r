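test_that("configuration validation and the equilibration heuristic", {
  expect_error(sim_config(scenario = "ibd"), "seed")
  expect_error(sim_config(selfing = 1.5, seed = 1))
  cfg <- sim_config(nx = 40, ny = 40, spacing = 1, sigma_seed = 1.8,
                    sigma_pollen = 3.07, seed = 1)
  expect_equal(cfg$sigma_g, sqrt(1.8^2 + 3.07^2 / 2))
  expect_equal(cfg$generations, ceiling(10 * 40 / cfg$sigma_g))
  expect_equal(sim_config(spacing = 2, seed = 1)$nx, 40)
})

test_that("a fixed seed fixes the whole dataset", {
  cfg <- sim_config(nx = 10, ny = 10, generations = 10, n_loci = 3,
                    scenario = "ibd", null_r = 0.1, seed = 77)
  d1 <- simulate_population(cfg)
  d2 <- simulate_population(cfg)
  expect_identical(d1, d2)
})

test_that("plastid inheritance is maternal: no new haplotypes without mutation", {
  cfg <- sim_config(nx = 12, ny = 12, generations = 30, n_hap = 30,
                    mu_hap = 0, scenario = "ibd", seed = 5)
  d <- simulate_population(cfg)
  # same seed, one generation: identical founders and first transmission,
  # so its haplotype pool contains every lineage the 30-generation world
  # can still carry (maternal descent can lose lineages, never invent them)
  cfg1 <- sim_config(nx = 12, ny = 12, generations = 1, n_hap = 30,
                     mu_hap = 0, scenario = "ibd", seed = 5)
  d1 <- simulate_population(cfg1)
  expect_true(all(d$haplotypes$haplotype %in% d1$haplotypes$haplotype))
  expect_lte(length(unique(d$haplotypes$haplotype)),
             length(unique(d1$haplotypes$haplotype)))
})

test_that("clonal reproduction copies the maternal genotype exactly", {
  cfg <- sim_config(nx = 8, ny = 8, generations = 20, clonal = 1, mu = 0,
                    mu_hap = 0, scenario = "ibd", n_loci = 3, seed = 6)
  d <- simulate_population(cfg)
  # with full clonality and no mutation every genotype descends unchanged
  # from a founder: heterozygosity pattern is frozen, so every multilocus
  # genotype present must occur among the founder genotype set
  cfg1 <- sim_config(nx = 8, ny = 8, generations = 1, clonal = 1, mu = 0,
                     mu_hap = 0, scenario = "ibd", n_loci = 3, seed = 6)
  d1 <- simulate_population(cfg1)
  key <- function(g) apply(cbind(pmin(g$a1, g$a2), pmax(g$a1, g$a2)), 1,
                           paste, collapse = ";")
  expect_true(all(key(d$genotypes) %in% key(d1$truth$genotypes_true)))
})

test_that("null-allele masking has the configured per-copy rate", {
  cfg <- sim_config(nx = 30, ny = 30, generations = 2, n_loci = 4,
                    null_r = c(0, 0.3, 0.1, 0), scenario = "panmixia",
                    seed = 9)
  d <- simulate_population(cfg)
  rate <- apply(d$truth$masked, 2, mean)
  expect_lt(max(abs(rate - c(0, 0.3, 0.1, 0))), 0.04)
  # both-copies-masked calls are missing; single-masked are homozygous
  miss <- colMeans(is.na(d$genotypes$a1))
  expect_lt(abs(miss[2] - 0.09), 0.03)
  expect_equal(unname(miss[c(1, 4)]), c(0, 0))
})

test_that("subsampling: identity, transect geometry, size check", {
  cfg <- sim_config(nx = 10, ny = 10, generations = 5, scenario = "panmixia",
                    seed = 12)
  d <- simulate_population(cfg)
  all_d <- sample_transect(d, 100, "random", seed = 1)
  expect_identical(all_d$genotypes, d$genotypes)
  expect_error(sample_transect(d, 101), "larger")

  tr <- sample_transect(d, 30, "transect")
  rd <- sample_transect(d, 30, "random", seed = 2)
  expect_lt(diff(range(tr$coords$y)), diff(range(rd$coords$y)))
})

test_that("panmictic worlds show no significant FSGS at the nominal rate", {
  p <- vapply(1:30, function(i) {
    cfg <- sim_config(nx = 15, ny = 15, generations = 5,
                      scenario = "panmixia", n_loci = 5, mu = 1e-3,
                      seed = 900 + i)
    d <- sample_transect(simulate_population(cfg), 50, "random", seed = i)
    correlogram(loiselle_kinship(d$genotypes), d$coords,
                n_perm = 99, seed = i)$p_slope
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.9)
})

test_that("stronger dispersal limitation gives larger Sp", {
  spof <- function(ss, sp, i) {
    cfg <- sim_config(nx = 40, ny = 40, sigma_seed = ss, sigma_pollen = sp,
                      generations = 100, scenario = "ibd", n_loci = 5,
                      mu = 1e-3, seed = 700 + i)
    d <- sample_transect(simulate_population(cfg), 80, "random", seed = i)
    correlogram(loiselle_kinship(d$genotypes), d$coords,
                n_perm = 49, seed = i)$Sp
  }
  sp_small <- vapply(1:5, function(i) spof(1.0, 1.5, i), numeric(1))
  sp_large <- vapply(1:5, function(i) spof(3.0, 5.0, i), numeric(1))
  expect_gt(median(sp_small), median(sp_large))
  expect_gt(median(sp_small), 0.005)
})

test_that("Sp is robust to transect versus random sampling of one world", {
  prs <- vapply(1:10, function(i) {
    cfg <- sim_config(nx = 40, ny = 40, generations = 100, scenario = "ibd",
                      sigma_seed = 0.8, sigma_pollen = 1.2, n_loci = 5,
                      mu = 1e-3, seed = 7000 + i)
    d <- simulate_population(cfg)
    spof <- function(dd, s)
      correlogram(loiselle_kinship(dd$genotypes), dd$coords,
                  n_perm = 49, seed = s)$Sp
    c(spof(sample_transect(d, 120, "random", seed = i), i),
      spof(sample_transect(d, 120, "transect"), i))
  }, numeric(2))
  rel <- abs(median(prs[2, ]) - median(prs[1, ])) / median(prs[1, ])
  expect_lt(rel, 0.5)
})
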