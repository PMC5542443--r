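# Spatially weighted PCA with global (G) and local (L) Monte-Carlo tests.

#' Build a spatial connection network
#'
#' Symmetric spatial weight matrix over individuals from one of three graph
#' rules: k-nearest neighbours (symmetrised by union), a distance
#' threshold, or the Gabriel graph (an edge i-j exists when no third point
#' lies inside the circle with diameter ij). The default is k = 10 nearest
#' neighbours, robust to the transect-like geometries common in field
#' sampling. The adjacency is kept symmetric; the Moran operator used by
#' [spca()] row-normalises it internally.
#'
#' @param s a `spatial_frame` with at least 3 individuals.
#' @param rule `"knn"`, `"distance"` or `"gabriel"`.
#' @param k neighbours for `"knn"`.
#' @param threshold distance cutoff in metres for `"distance"`.
#' @return an object of class `connection_network`: list with `W` (0/1
#'   symmetric adjacency, zero diagonal), `rule`, `n_components`.
#' @export
build_network <- function(s, rule = c("knn", "distance", "gabriel"),
                          k = 10, threshold = NULL) {
  rule <- match.arg(rule)
  n <- nrow(s)
  if (n < 3) stop("need at least 3 individuals")
  d <- pair_distances(s)
  W <- matrix(0, n, n)
  if (rule == "knn") {
    k <- min(k, n - 1)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1)]
      W[i, nb] <- 1
    }
    W <- pmax(W, t(W))               # symmetrise by union
  } else if (rule == "distance") {
    if (is.null(threshold)) stop("distance rule needs a threshold")
    W <- (d > 0 & d <= threshold) * 1
  } else {
    # Gabriel graph: midpoint circle empty of third points
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      mx <- (s$x[i] + s$x[j]) / 2; my <- (s$y[i] + s$y[j]) / 2
      r2 <- (d[i, j] / 2)^2
      others <- setdiff(seq_len(n), c(i, j))
      if (all((s$x[others] - mx)^2 + (s$y[others] - my)^2 > r2 + 1e-12))
        W[i, j] <- W[j, i] <- 1
    }
  }
  diag(W) <- 0
  # connected components by BFS on the adjacency
  comp <- integer(n); cc <- 0L
  for (i in seq_len(n)) if (comp[i] == 0L) {
    cc <- cc + 1L; queue <- i; comp[i] <- cc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cc; queue <- c(queue, nb)
    }
  }
  if (cc > 1L) warning("connection network has ", cc, " components")
  structure(list(W = W, rule = rule, n_components = cc, ids = s$id),
            class = "connection_network")
}

# centred, mean-imputed dosage matrix (missing -> column mean, i.e. 0 after
# centring) plus the row-normalised weight matrix
spca_inputs <- function(g, w) {
  X <- if (is.matrix(g)) g else dosage_matrix(g)$X
  if (ncol(X) < 2) stop("fewer than 2 allele columns")
  p <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2, p)
  Xc[is.na(Xc)] <- 0
  W <- if (inherits(w, "connection_network")) w$W else w
  rs <- rowSums(W)
  Wn <- W / ifelse(rs > 0, rs, 1)
  list(X = Xc, W = Wn)
}

#' Spatially weighted principal component analysis
#'
#' Eigen-decomposition of the spatially lagged covariance operator
#' \deqn{C = \frac{1}{2n} X^T (W + W^T) X}
#' with X the column-centred allele-dosage matrix (missing values
#' mean-imputed) and W the row-normalised connection network. Positive
#' eigenvalues capture axes combining large variance with positive spatial
#' autocorrelation ("global" structure: clines, patches); negative
#' eigenvalues capture negative autocorrelation ("local" structure:
#' differentiation between neighbours). Scores are the projections X v,
#' with the sign convention that each axis correlates non-negatively with
#' the x-coordinate (or y if degenerate).
#'
#' @param g a `genotype_matrix` (or a pre-built dosage matrix).
#' @param w a `connection_network` (or a raw weight matrix; passing the
#'   identity recovers ordinary PCA of the dosages up to the 1/n scale).
#' @param s optional `spatial_frame` used only for the sign convention.
#' @return an object of class `spca_result`: list with `eigenvalues`
#'   (sorted decreasing), `eig_spca` (leading positive eigenvalue),
#'   `scores` (individuals x axes), `vectors`.
#' @export
spca <- function(g, w, s = NULL) {
  inp <- spca_inputs(g, w)
  n <- nrow(inp$X)
  Wsym <- (inp$W + t(inp$W))
  C <- crossprod(inp$X, Wsym %*% inp$X) / (2 * n)
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  scores <- inp$X %*% e$vectors
  if (!is.null(s)) {
    for (j in seq_len(ncol(scores))) {
      cc <- suppressWarnings(stats::cor(scores[, j], s$x))
      if (is.na(cc) || cc == 0)
        cc <- suppressWarnings(stats::cor(scores[, j], s$y))
      if (!is.na(cc) && cc < 0) {
        scores[, j] <- -scores[, j]; e$vectors[, j] <- -e$vectors[, j]
      }
    }
  }
  pos <- e$values[e$values > 1e-12]
  structure(list(eigenvalues = e$values,
                 eig_spca = if (length(pos)) pos[1] else 0,
                 scores = scores, vectors = e$vectors),
            class = "spca_result")
}

#' Global (G) and local (L) Monte-Carlo tests for spatial structure
#'
#' The G statistic is the summed positive-eigenvalue mass of the sPCA
#' operator and the L statistic the summed absolute negative mass; their
#' null distributions come from permuting whole genotype rows across
#' spatial locations. One-sided P-values use (extreme + 1)/(n_perm + 1).
#' These are permutation analogues of the original spectral G/L tests;
#' their calibration (uniform null P) is checked in the test suite.
#'
#' @inheritParams spca
#' @param n_perm number of permutations (>= 99 recommended).
#' @param seed RNG seed (required).
#' @return list with `G`, `L`, `p_G`, `p_L`, `n_perm`.
#' @export
g_l_tests <- function(g, w, n_perm = 999, seed) {
  if (missing(seed)) stop("an explicit RNG seed is required")
  if (n_perm < 99) warning("fewer than 99 permutations")
  inp <- spca_inputs(g, w)
  n <- nrow(inp$X)
  Wsym <- inp$W + t(inp$W)
  gl_of <- function(X) {
    C <- crossprod(X, Wsym %*% X) / (2 * n)
    ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
    c(G = sum(ev[ev > 0]), L = sum(-ev[ev < 0]))
  }
  obs <- gl_of(inp$X)
  set.seed(seed)
  null <- t(vapply(seq_len(n_perm), function(i) gl_of(inp$X[sample(n), ]),
                   numeric(2)))
  list(G = obs[["G"]], L = obs[["L"]],
       p_G = (sum(null[, 1] >= obs[["G"]]) + 1) / (n_perm + 1),
       p_L = (sum(null[, 2] >= obs[["L"]]) + 1) / (n_perm + 1),
       n_perm = n_perm)
}
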