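# Shared helpers: random genotype generators and independently coded oracles
# used across the test files.

# HWE genotypes: alleles drawn i.i.d. uniform over `nal` labels
rand_geno <- function(n, L, nal, seed) {
  set.seed(seed)
  al <- function() matrix(as.character(sample.int(nal, n * L, TRUE)), n, L)
  genotype_matrix(paste0("i", seq_len(n)), paste0("L", seq_len(L)),
                  al(), al())
}

rand_coords <- function(g, extent = 100, seed = 1) {
  set.seed(seed)
  n <- length(g$ids)
  spatial_frame(g$ids, stats::runif(n, 0, extent), stats::runif(n, 0, extent))
}

# Brute-force Loiselle oracle, written scalar-by-scalar from the estimator
# definition (independent of the package's vectorised implementation)
loiselle_oracle <- function(g) {
  n <- length(g$ids)
  Fm <- matrix(NA_real_, n, n)
  num_tot <- matrix(0, n, n); den_tot <- matrix(0, n, n)
  for (l in seq_along(g$loci)) {
    a1 <- g$a1[, l]; a2 <- g$a2[, l]
    typed <- !is.na(a1)
    alleles <- sort(unique(c(a1[typed], a2[typed])))
    nl <- 2 * sum(typed)
    if (nl < 2 || length(alleles) < 2) next
    p <- vapply(alleles, function(a)
      (sum(a1[typed] == a) + sum(a2[typed] == a)) / nl, numeric(1))
    den_l <- sum(p * (1 - p))
    x <- function(i, a) (as.numeric(a1[i] == a) + as.numeric(a2[i] == a)) / 2
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (!typed[i] || !typed[j]) next
      s <- 0
      for (k in seq_along(alleles)) {
        a <- alleles[k]
        s <- s + (x(i, a) - p[k]) * (x(j, a) - p[k]) +
          p[k] * (1 - p[k]) / (nl - 1)
      }
      num_tot[i, j] <- num_tot[i, j] + s
      den_tot[i, j] <- den_tot[i, j] + den_l
    }
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (den_tot[i, j] > 0) Fm[i, j] <- Fm[j, i] <- num_tot[i, j] / den_tot[i, j]
  Fm
}

# exhaustive rarefaction oracle: mean distinct alleles over all C(N, g)
# gene-copy subsamples
rarefaction_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
}

# psex by direct summation of the binomial tail
psex_oracle <- function(p_gen, N, k) {
  j <- (k - 1):(N - 1)
  sum(choose(N - 1, j) * p_gen^j * (1 - p_gen)^(N - 1 - j))
}
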