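# The association-test battery: F_ST among gene pools, cyto-nuclear
# disequilibrium, morphotype/altitude associations, continental contrasts.

#' Weir-Cockerham F_ST among gene pools with a permutation test
#'
#' Multilocus Weir & Cockerham (1984) theta by ratio of summed variance
#' components (a over a+b+c, summed over alleles and loci). The null
#' distribution permutes group labels over individuals. Unlabelled
#' individuals (`NA`, e.g. UNASSIGNED at a Q threshold) are dropped first.
#'
#' @param g a `genotype_matrix`.
#' @param labels group label per individual (`NA` dropped).
#' @param n_perm permutations (default 9999).
#' @param seed RNG seed (required when `n_perm > 0`).
#' @return list with `Fst`, `p` (one-sided, observed or larger),
#'   `group_sizes`.
#' @export
fst_among_pools <- function(g, labels, n_perm = 9999, seed) {
  labels <- as.vector(labels)
  keep <- which(!is.na(labels))
  labels <- as.factor(labels[keep])
  sizes <- table(labels)
  if (sum(sizes >= 2) < 2)
    stop("F_ST undefined: need >= 2 groups with >= 2 members")
  gg <- subset_genotypes(g, keep)
  obs <- wc_theta(gg, labels)
  p <- NA_real_
  if (n_perm > 0) {
    if (missing(seed)) stop("an explicit RNG seed is required")
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i)
      wc_theta(gg, sample(labels)), numeric(1))
    p <- (sum(null >= obs) + 1) / (n_perm + 1)
  }
  list(Fst = obs, p = p, group_sizes = sizes)
}

# Weir & Cockerham (1984) theta, multilocus ratio of summed components
wc_theta <- function(g, labels) {
  labels <- as.factor(labels)
  a_sum <- 0; bc_sum <- 0
  for (j in seq_along(g$loci)) {
    a1 <- g$a1[, j]; a2 <- g$a2[, j]
    ok <- !is.na(a1)
    if (sum(ok) < 2) next
    lab <- droplevels(labels[ok])
    if (nlevels(lab) < 2) next
    al1 <- a1[ok]; al2 <- a2[ok]
    ni <- as.numeric(table(lab))            # individuals per pop
    r <- length(ni)
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    alleles <- unique(c(al1, al2))
    for (al in alleles) {
      x1 <- (al1 == al); x2 <- (al2 == al)
      pi <- tapply((x1 + x2) / 2, lab, mean)          # freq per pop
      hi <- tapply(x1 != x2 & (x1 | x2), lab, mean)   # het-for-allele per pop
      pbar <- sum(ni * pi) / sum(ni)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / sum(ni)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      a_sum <- a_sum + a; bc_sum <- bc_sum + b + cc
    }
  }
  a_sum / (a_sum + bc_sum)
}

#' One-way ANOVA of individual sPCA scores across groups
#'
#' Tests whether groups of individuals (e.g. carriers of the same plastid
#' haplotype, or members of the same altitudinal class) differ in their
#' mean score on an sPCA axis. Groups with fewer than 2 members are
#' dropped with a warning.
#'
#' @param scores numeric vector of per-individual scores.
#' @param groups categorical group label per individual.
#' @return object of class `association_test`: list with `family`
#'   (`"anova"`), `statistic` (F), `df`, `p`, `group_means`.
#' @export
anova_scores <- function(scores, groups) {
  groups <- as.factor(groups)
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]; groups <- droplevels(groups[keep])
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("dropping ", sum(sizes < 2), " group(s) with fewer than 2 members")
    ok <- groups %in% names(sizes[sizes >= 2])
    scores <- scores[ok]; groups <- droplevels(groups[ok])
  }
  if (nlevels(groups) < 2) stop("need >= 2 groups with >= 2 members")
  fit <- stats::anova(stats::lm(scores ~ groups))
  structure(list(family = "anova",
                 statistic = fit$`F value`[1],
                 df = fit$Df,
                 p = fit$`Pr(>F)`[1], p_type = "analytic",
                 group_means = tapply(scores, groups, mean)),
            class = "association_test")
}

#' Fisher association test for an r x c contingency table
#'
#' 2x2 tables use the exact two-sided hypergeometric test; larger tables
#' use a Monte-Carlo test over tables sampled with fixed margins
#' (Patefield's algorithm via [stats::r2dtable()]), with P =
#' (extreme + 1)/(n_mc + 1) counting sampled tables whose probability does
#' not exceed the observed table's.
#'
#' @param table matrix of non-negative integer counts.
#' @param n_mc Monte-Carlo draws for tables larger than 2x2.
#' @param seed RNG seed (required for the Monte-Carlo branch).
#' @param force_mc use the Monte-Carlo branch even on a 2x2 table (lets the
#'   sampler be validated against the exact result).
#' @return an `association_test` with `p_type` `"exact"` or `"monte_carlo"`.
#' @export
fisher_association <- function(table, n_mc = 1e5, seed, force_mc = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin in contingency table")
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need >= 2 categories on both margins")
  if (nrow(table) == 2 && ncol(table) == 2 && !force_mc) {
    p <- stats::fisher.test(table)$p.value
    type <- "exact"
  } else {
    if (missing(seed)) stop("an explicit RNG seed is required")
    set.seed(seed)
    lp_obs <- table_logprob(table)
    sim <- stats::r2dtable(n_mc, rowSums(table), colSums(table))
    lp <- vapply(sim, table_logprob, numeric(1))
    p <- (sum(lp <= lp_obs + 1e-9) + 1) / (n_mc + 1)
    type <- "monte_carlo"
  }
  structure(list(family = "fisher", statistic = NA_real_, p = p,
                 p_type = type, table = table),
            class = "association_test")
}

# log hypergeometric probability of a table with fixed margins
table_logprob <- function(tb) {
  sum(lgamma(rowSums(tb) + 1)) + sum(lgamma(colSums(tb) + 1)) -
    lgamma(sum(tb) + 1) - sum(lgamma(tb + 1))
}

#' Partial Mantel test with spatial-distance control
#'
#' Correlation between the off-diagonal entries of two similarity matrices
#' (conventionally 1 for pairs sharing a haplotype or gene pool, 0
#' otherwise), partialling out a control matrix (spatial distance):
#' \deqn{r_{ab.c} = (r_{ab} - r_{ac} r_{bc}) /
#'   \sqrt{(1-r_{ac}^2)(1-r_{bc}^2)}.}
#' The null permutes rows and columns of the first matrix jointly and
#' recomputes the partial correlation; the one-sided P is for positive
#' association. A constant control matrix reduces the statistic to the
#' simple Mantel correlation.
#'
#' @param sim_a,sim_b square symmetric matrices with matching ids.
#' @param control square symmetric control matrix (e.g. pairwise distance).
#' @param n_perm permutations (default 9999).
#' @param seed RNG seed (required).
#' @return an `association_test` with `statistic` = r_ab.c.
#' @export
partial_mantel <- function(sim_a, sim_b, control, n_perm = 9999, seed) {
  if (missing(seed)) stop("an explicit RNG seed is required")
  stopifnot(identical(dim(sim_a), dim(sim_b)),
            identical(dim(sim_a), dim(control)))
  ut <- upper.tri(sim_a)
  b <- sim_b[ut]; cv <- control[ut]
  if (stats::sd(sim_a[ut]) == 0 || stats::sd(b) == 0)
    stop("constant similarity matrix: Mantel statistic undefined")
  partial_r <- function(av) {
    if (stats::sd(cv) == 0) return(stats::cor(av, b))   # simple Mantel
    r_ab <- stats::cor(av, b); r_ac <- stats::cor(av, cv)
    r_bc <- stats::cor(b, cv)
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  obs <- partial_r(sim_a[ut])
  set.seed(seed)
  n <- nrow(sim_a)
  null <- vapply(seq_len(n_perm), function(i) {
    p <- sample(n)
    partial_r(sim_a[p, p][ut])
  }, numeric(1))
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  structure(list(family = "partial_mantel", statistic = obs, p = p,
                 p_type = "monte_carlo", n_perm = n_perm),
            class = "association_test")
}

#' Build a 0/1 same-label similarity matrix
#' @param labels categorical label per individual (`NA` gives `NA` rows).
#' @return symmetric 0/1 matrix, diagonal 1.
#' @export
similarity_matrix <- function(labels) {
  outer(labels, labels, function(a, b) as.numeric(a == b))
}

#' Pooled-variance one-tailed two-sample t-test
#'
#' Student t with pooled variance and df = n_a + n_b - 2, one-tailed in
#' the direction group_a > group_b. Used for continental contrasts of
#' per-population FSGS statistics (Sp, eig.sPCA).
#'
#' @param group_a,group_b numeric vectors (each >= 2 values).
#' @return an `association_test` with `statistic` = t and `p`.
#' @export
continental_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 values")
  if (stats::var(group_a) + stats::var(group_b) == 0)
    stop("zero pooled variance")
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE,
                      alternative = "greater")
  if (!is.finite(tt$statistic)) stop("zero pooled variance")
  structure(list(family = "ttest", statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 p_type = "analytic",
                 group_means = c(a = mean(group_a), b = mean(group_b))),
            class = "association_test")
}

#' Spearman rank correlation with exact small-sample P
#'
#' Spearman's rho on midranks. For n <= 10 the one-sided P
#' (positive association) is exact, by full enumeration of all n! rank
#' permutations: P = #\{permutations with rho >= observed\}/n!. For larger
#' n the asymptotic t approximation is used.
#'
#' @param x,y numeric vectors of equal length.
#' @return an `association_test` with `statistic` = rho, `p`, and
#'   `p_type` `"exact"` (with `denominator` = n!) or `"analytic"`.
#' @export
spearman_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rho undefined")
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10) {
    P <- all_permutations(n)
    # rho is monotone increasing in sum(rx * ry[sigma]) at fixed margins
    obs <- sum(rx * ry)
    # P rows are permutations sigma; score = sum_i rx[i] * ry[sigma[i]]
    scores <- as.vector(matrix(ry[t(P)], ncol = n, byrow = TRUE) %*% rx)
    cnt <- sum(scores >= obs - 1e-9)
    p <- cnt / nrow(P)
    structure(list(family = "spearman", statistic = rho, p = p,
                   p_type = "exact", denominator = factorial(n),
                   count = cnt),
              class = "association_test")
  } else {
    p <- stats::cor.test(x, y, method = "spearman", exact = FALSE,
                         alternative = "greater")$p.value
    structure(list(family = "spearman", statistic = rho, p = p,
                   p_type = "analytic"),
              class = "association_test")
  }
}

# all permutations of 1..n as an n! x n matrix (recursive construction)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    m <- sub
    m[m >= k] <- m[m >= k] + 1L
    cbind(rep(k, nrow(m)), m)
  }))
}

#' @export
print.association_test <- function(x, ...) {
  cat(x$family, "test: statistic =",
      if (is.na(x$statistic)) "(exact)" else signif(x$statistic, 4),
      " P =", signif(x$p, 4), paste0("(", x$p_type, ")"), "\n")
  invisible(x)
}
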