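# Bayesian admixture clustering: Gibbs sampler over latent allele-copy
# origins z, cluster allele frequencies P (Dirichlet prior) and individual
# ancestries Q (Dirichlet(alpha) prior, alpha updated by Metropolis).

# flatten a genotype matrix into per-gene-copy records with integer allele
# codes and a column offset per locus into a K x sum(J_l) frequency matrix
admix_prepare <- function(g) {
  n <- length(g$ids); L <- length(g$loci)
  levs <- lapply(seq_len(L), function(j)
    sort(unique(c(g$a1[, j], g$a2[, j])), na.last = NA))
  J <- lengths(levs)
  off <- c(0L, cumsum(J))[seq_len(L)]
  recs <- lapply(seq_len(L), function(j) {
    a1 <- match(g$a1[, j], levs[[j]]); a2 <- match(g$a2[, j], levs[[j]])
    ok <- !is.na(a1)
    data.frame(i = rep(which(ok), 2),
               col = off[j] + c(a1[ok], a2[ok]))
  })
  recs <- do.call(rbind, recs)
  list(n = n, L = L, J = J, off = off, levs = levs,
       i = recs$i, col = recs$col, sumJ = sum(J))
}

rdirichlet_rows <- function(shape) {
  gm <- matrix(stats::rgamma(length(shape), shape = shape), nrow = nrow(shape))
  gm / rowSums(gm)
}

# --- Gibbs conditional updates (shared by the sampler and by the
# sampler-validity tests, which drive them inside a marginal/successive
# simulator comparison) ----------------------------------------------------

# z | Q, P: cluster origin of every gene copy, plus the log-likelihood of
# the data under the current (Q, P)
admix_update_z <- function(i_vec, col_vec, Q, Pmat) {
  M <- length(i_vec); K <- ncol(Q)
  probM <- Q[i_vec, , drop = FALSE] * t(Pmat)[col_vec, , drop = FALSE]
  tot <- rowSums(probM)
  r <- stats::runif(M) * tot
  cs <- probM[, 1]
  z <- rep(1L, M)
  if (K > 1) for (k in 2:K) {
    z <- z + (cs < r)
    cs <- cs + probM[, k]
  }
  list(z = z, loglik = sum(log(tot)))
}

# P | z: Dirichlet per cluster x locus block
admix_update_P <- function(z, col_vec, K, sumJ, block, lambda) {
  cnt_P <- matrix(tabulate((col_vec - 1L) * K + z, nbins = K * sumJ),
                  nrow = K)
  Pg <- matrix(stats::rgamma(K * sumJ, shape = lambda + cnt_P), nrow = K)
  norm <- t(rowsum(t(Pg), block))              # K x n_loci block sums
  Pg / norm[, block, drop = FALSE]
}

# Q | z: Dirichlet per individual
admix_update_Q <- function(z, i_vec, n, K, alpha) {
  cnt_Q <- t(matrix(tabulate((i_vec - 1L) * K + z, nbins = n * K),
                    nrow = K))
  rdirichlet_rows(alpha + cnt_Q)
}

# alpha | Q: Metropolis with uniform(0, alpha_max] prior
admix_update_alpha <- function(Q, alpha, alpha_sd, alpha_max) {
  n <- nrow(Q); K <- ncol(Q)
  prop <- alpha + stats::rnorm(1, 0, alpha_sd)
  if (prop > 0 && prop <= alpha_max) {
    lr <- n * (lgamma(K * prop) - K * lgamma(prop) -
                 lgamma(K * alpha) + K * lgamma(alpha)) +
      (prop - alpha) * sum(log(pmax(Q, 1e-300)))
    if (log(stats::runif(1)) < lr) return(prop)
  }
  alpha
}

# one replicate of the Gibbs sampler; returns posterior-mean Q and P,
# log-likelihood and alpha traces, and the L(K) estimate mean(D) - var(D)/2
admix_gibbs <- function(prep, K, burnin, iters, lambda = 1,
                        alpha0 = 1, alpha_sd = 0.025, alpha_max = 10) {
  n <- prep$n; sumJ <- prep$sumJ
  Pmat <- matrix(1 / rep(prep$J, prep$J), nrow = K, ncol = sumJ, byrow = TRUE)
  Q <- matrix(1 / K, n, K)
  alpha <- alpha0
  Qsum <- matrix(0, n, K); Psum <- matrix(0, K, sumJ)
  D_trace <- numeric(iters); a_trace <- numeric(iters)
  n_keep <- 0L
  block <- rep(seq_len(prep$L), prep$J)
  for (it in seq_len(iters)) {
    up <- admix_update_z(prep$i, prep$col, Q, Pmat)
    D_trace[it] <- up$loglik
    Pmat <- admix_update_P(up$z, prep$col, K, sumJ, block, lambda)
    Q <- admix_update_Q(up$z, prep$i, n, K, alpha)
    if (K > 1)
      alpha <- admix_update_alpha(Q, alpha, alpha_sd, alpha_max)
    a_trace[it] <- alpha
    if (it > burnin) {
      Qsum <- Qsum + Q; Psum <- Psum + Pmat; n_keep <- n_keep + 1L
    }
  }
  post <- D_trace[(burnin + 1):iters]
  list(Q = Qsum / n_keep, P = Psum / n_keep,
       loglik = D_trace, alpha = a_trace,
       L = mean(post) - stats::var(post) / 2)
}

#' Run STRUCTURE-style admixture clustering
#'
#' Gibbs sampler for the admixture model with independent Dirichlet
#' (`lambda = 1`) allele frequencies per cluster: latent cluster origins of
#' every gene copy, cluster allele frequencies P, individual ancestry
#' vectors Q with a symmetric Dirichlet(alpha) prior whose concentration
#' alpha is updated by a Metropolis step (uniform prior on (0, 10],
#' proposal SD 0.025). Point estimates are posterior means after burn-in;
#' the model log-probability L(K) uses the standard
#' `mean(D) - var(D)/2` estimator on the post-burn-in log-likelihood trace.
#' Missing alleles are skipped. Replicate runs are aligned by greedy
#' matching of cluster columns (maximal Q correlation); alignment never
#' changes L(K) or assignment proportions.
#'
#' @param g a `genotype_matrix`.
#' @param K number of clusters.
#' @param burnin burn-in sweeps.
#' @param iters total sweeps (posterior from sweeps `burnin+1 .. iters`).
#' @param n_reps independent replicate chains.
#' @param seed RNG seed (required).
#' @param lambda Dirichlet parameter for allele frequencies.
#' @param alpha_sd,alpha_max Metropolis proposal SD and prior upper bound
#'   for alpha.
#' @return object of class `admixture_result`: list with `K`, `Q`
#'   (posterior-mean ancestry averaged over aligned replicates), `L`
#'   (per-replicate L(K)), `replicates` (full per-replicate output),
#'   `alpha_warning` (TRUE when the alpha trace shows a post-burn-in trend).
#' @export
run_admixture <- function(g, K, burnin = 20000, iters = 80000, n_reps = 1,
                          seed, lambda = 1, alpha_sd = 0.025, alpha_max = 10) {
  if (missing(seed)) stop("an explicit RNG seed is required")
  stopifnot(K >= 1, iters > burnin, burnin >= 0)
  prep <- admix_prepare(g)
  set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(r)
    admix_gibbs(prep, K, burnin, iters, lambda = lambda,
                alpha_sd = alpha_sd, alpha_max = alpha_max))
  # align replicate clusters to the first by greedy Q-correlation matching
  if (n_reps > 1 && K > 1) {
    ref <- reps[[1]]$Q
    for (r in 2:n_reps) {
      perm <- align_clusters(ref, reps[[r]]$Q)
      reps[[r]]$Q <- reps[[r]]$Q[, perm, drop = FALSE]
      reps[[r]]$P <- reps[[r]]$P[perm, , drop = FALSE]
    }
  }
  Qbar <- Reduce(`+`, lapply(reps, `[[`, "Q")) / n_reps
  rownames(Qbar) <- g$ids
  # alpha convergence: trend over the post-burn-in trace
  awarn <- any(vapply(reps, function(rr) {
    a <- rr$alpha[(burnin + 1):iters]
    if (stats::sd(a) == 0) return(FALSE)
    t3 <- seq_along(a)
    fit <- stats::lm.fit(cbind(1, t3), a)
    slope <- fit$coefficients[2]
    abs(slope) * length(a) > 3 * stats::sd(a)   # drift > 3 SD over the trace
  }, logical(1)))
  if (awarn) warning("alpha trace shows a trend: chain may not have converged")
  structure(list(K = K, Q = Qbar, L = vapply(reps, `[[`, numeric(1), "L"),
                 replicates = reps, ids = g$ids, alpha_warning = awarn,
                 burnin = burnin, iters = iters),
            class = "admixture_result")
}

# greedy permutation matching columns of Q2 to Q1 by maximal correlation:
# repeatedly pick the highest remaining (reference, candidate) pair
align_clusters <- function(Q1, Q2) {
  K <- ncol(Q1)
  cm <- suppressWarnings(stats::cor(Q1, Q2))
  cm[is.na(cm)] <- 0
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- arrayInd(which.max(cm), dim(cm))
    perm[idx[1]] <- idx[2]
    cm[idx[1], ] <- -Inf
    cm[, idx[2]] <- -Inf
  }
  perm
}

#' Model-order selection: L(K) and the Evanno Delta-K
#'
#' From replicate runs over a grid of K, reports per K the mean and SD of
#' L(K) over replicates and
#' \deqn{\Delta K = |L(K-1) - 2 L(K) + L(K+1)| / sd(L(K))}
#' (means of L across replicates in the numerator; defined only for
#' interior K with replicate SD > 0). Both criteria are reported; a
#' disagreement between the K maximising L(K) and the K maximising Delta-K
#' is flagged, never auto-resolved.
#'
#' @param results list of `admixture_result` objects over consecutive K.
#' @return object of class `k_selection`: list with `table` (K, mean_L,
#'   sd_L, delta_K), `best_L`, `best_deltaK`, `conflict`.
#' @export
select_k <- function(results) {
  Ks <- vapply(results, `[[`, numeric(1), "K")
  o <- order(Ks); results <- results[o]; Ks <- Ks[o]
  mean_L <- vapply(results, function(r) mean(r$L), numeric(1))
  sd_L <- vapply(results, function(r) stats::sd(r$L), numeric(1))
  dK <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)) {
    if (i == 1 || i == length(Ks)) next
    if (is.na(sd_L[i]) || sd_L[i] == 0) next
    dK[i] <- abs(mean_L[i - 1] - 2 * mean_L[i] + mean_L[i + 1]) / sd_L[i]
  }
  tab <- data.frame(K = Ks, mean_L = mean_L, sd_L = sd_L, delta_K = dK)
  best_L <- Ks[which.max(mean_L)]
  best_dK <- if (all(is.na(dK))) NA_integer_ else Ks[which.max(dK)]
  structure(list(table = tab, best_L = best_L, best_deltaK = best_dK,
                 conflict = !is.na(best_dK) && best_dK != best_L),
            class = "k_selection")
}

#' Assign individuals to gene pools by an ancestry threshold
#'
#' An individual is assigned to its argmax-Q cluster when that Q meets the
#' threshold, and is otherwise UNASSIGNED (`NA`). The conventional
#' thresholds are 0.5 and 0.875, the latter admitting pure individuals,
#' first-generation and later backcrosses.
#'
#' @param r an `admixture_result` with `K >= 2`.
#' @param threshold ancestry threshold (0.5 or 0.875 conventionally).
#' @return list with `label` (cluster index per individual, `NA` when
#'   unassigned), `pct_assigned` (the PI50/PI87-style percentage).
#' @export
assign_gene_pools <- function(r, threshold = 0.5) {
  stopifnot(r$K >= 2)
  best <- max.col(r$Q, ties.method = "first")
  q <- r$Q[cbind(seq_len(nrow(r$Q)), best)]
  lab <- ifelse(q >= threshold, best, NA_integer_)
  list(label = stats::setNames(lab, r$ids),
       pct_assigned = 100 * mean(!is.na(lab)))
}
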