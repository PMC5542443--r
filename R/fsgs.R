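# Kinship correlogram, permutation tests and the Sp statistic.

#' Loiselle pairwise kinship coefficients
#'
#' The Loiselle et al. (1995) kinship estimator with the sample's own allele
#' frequencies as reference. For locus l with allele frequencies p_a and
#' n_l gene copies typed, the per-allele numerator between individuals i
#' and j is
#' \deqn{(x_{ia} - p_a)(x_{ja} - p_a) + p_a (1 - p_a)/(n_l - 1)}
#' with x the within-individual allele frequency (0, 1/2, 1 for diploids;
#' 0/1 for haploid data), and the denominator is \eqn{\sum_a p_a (1-p_a)}.
#' The multilocus estimate is the ratio of locus-summed numerators to
#' locus-summed denominators; per-locus matrices are retained for the
#' delete-one-locus jackknife.
#'
#' @param g a `genotype_matrix`, or a `haplotype_set` (treated as one
#'   haploid locus).
#' @return an object of class `kinship_matrix`: list with `F` (the
#'   multilocus symmetric matrix, diagonal `NA`), `num`/`den` (per-locus
#'   numerator arrays and denominators for the jackknife), `loci`, `ids`.
#'   Pairs with no co-typed locus are `NA`.
#' @export
loiselle_kinship <- function(g) {
  if (inherits(g, "haplotype_set")) {
    ids <- g$ids
    hap <- g$haplotype
    levs <- sort(unique(hap[!is.na(hap)]))
    X <- matrix(0, length(ids), length(levs), dimnames = list(ids, levs))
    X[cbind(seq_along(hap), match(hap, levs))] <- 1
    X[is.na(hap), ] <- NA
    locus_of <- rep(1L, length(levs))
    loci <- "plastid"
  } else {
    dm <- dosage_matrix(g)
    X <- dm$X; locus_of <- dm$locus; ids <- g$ids; loci <- g$loci
  }
  n_ind <- nrow(X)
  L <- max(locus_of)
  num <- array(NA_real_, c(n_ind, n_ind, L))
  den <- numeric(L)
  for (l in seq_len(L)) {
    cols <- which(locus_of == l)
    Xl <- X[, cols, drop = FALSE]
    typed <- !is.na(Xl[, 1])
    nl <- if (inherits(g, "haplotype_set")) sum(typed) else 2 * sum(typed)
    if (nl < 2) { den[l] <- 0; next }
    p <- colMeans(Xl[typed, , drop = FALSE])
    pq <- sum(p * (1 - p))
    if (pq == 0) { den[l] <- 0; num[, , l] <- 0; next }
    Xc <- sweep(Xl, 2, p)
    Xc[!typed, ] <- 0
    cross <- tcrossprod(Xc)                       # sum_a (x_ia-p)(x_ja-p)
    corr <- sum(p * (1 - p)) / (nl - 1)
    numl <- cross + corr
    numl[!typed, ] <- NA; numl[, !typed] <- NA
    num[, , l] <- numl
    den[l] <- pq
  }
  if (all(den == 0)) stop("no polymorphic locus: kinship undefined")
  num_sum <- apply(num, c(1, 2), function(v) {
    ok <- !is.na(v) & den > 0
    if (!any(ok)) NA_real_ else sum(v[ok])
  })
  den_sum <- apply(num, c(1, 2), function(v) sum(den[!is.na(v) & den > 0]))
  Fm <- num_sum / ifelse(den_sum > 0, den_sum, NA)
  diag(Fm) <- NA
  dimnames(Fm) <- list(ids, ids)
  structure(list(F = Fm, num = num, den = den, ids = ids, loci = loci),
            class = "kinship_matrix")
}

# multilocus kinship dropping locus `drop` (for jackknife)
kinship_drop_locus <- function(k, drop) {
  keep <- setdiff(seq_along(k$den), drop)
  num_sum <- apply(k$num[, , keep, drop = FALSE], c(1, 2), function(v) {
    ok <- !is.na(v) & k$den[keep] > 0
    if (!any(ok)) NA_real_ else sum(v[ok])
  })
  den_sum <- apply(k$num[, , keep, drop = FALSE], c(1, 2),
                   function(v) sum(k$den[keep][!is.na(v) & k$den[keep] > 0]))
  Fm <- num_sum / ifelse(den_sum > 0, den_sum, NA)
  diag(Fm) <- NA
  Fm
}

#' Build a distance-class scheme with SPAGeDi-style diagnostics
#'
#' Class upper bounds are quantiles of the pairwise distances (equal pair
#' counts per class). Diagnostics follow the usual recommendations: similar
#' pair counts across classes, more than 50% of individuals represented in
#' every class, and a coefficient of variation below 1 of the number of
#' times each individual appears in each class. A scheme failing the
#' criteria is returned with `valid = FALSE` and a rejection report
#' (suggesting fewer classes) rather than an error. Co-located pairs
#' (distance 0) are assigned to the first class.
#'
#' @param s a `spatial_frame`.
#' @param n_classes number of distance classes.
#' @param bounds optional explicit upper bounds (overrides the quantiles).
#' @return an object of class `distance_classes`: list with `bounds`,
#'   `class` (per-pair class index matrix), `diagnostics` (per class:
#'   `pairs`, `pct_individuals`, `cv_participation`), `valid`, `report`.
#' @export
build_distance_classes <- function(s, n_classes, bounds = NULL) {
  d <- pair_distances(s)
  n <- nrow(d)
  ut <- upper.tri(d)
  dv <- d[ut]
  if (n_classes > length(dv)) stop("more classes than pairs")
  if (max(dv) == 0) {
    return(structure(list(
      bounds = 0, class = ifelse(ut | t(ut), 1L, NA),
      diagnostics = data.frame(class = 1L, pairs = sum(ut),
                               pct_individuals = 100, cv_participation = 0),
      valid = FALSE,
      report = "all locations identical: single degenerate class"),
      class = "distance_classes"))
  }
  if (is.null(bounds)) {
    bounds <- unique(stats::quantile(dv[dv > 0],
                                     probs = seq_len(n_classes) / n_classes,
                                     names = FALSE))
    bounds[length(bounds)] <- max(dv)
  }
  cls <- matrix(NA_integer_, n, n)
  idx <- findInterval(dv, bounds, left.open = TRUE) + 1L
  idx[dv == 0] <- 1L
  idx[idx > length(bounds)] <- length(bounds)
  cls[ut] <- idx
  cls[lower.tri(cls)] <- t(cls)[lower.tri(cls)]
  diag <- lapply(seq_along(bounds), function(k) {
    sel <- which(cls == k, arr.ind = TRUE)
    part <- tabulate(sel[, 1], nbins = n)   # both triangles: count per indiv
    data.frame(class = k, upper = bounds[k], pairs = nrow(sel) / 2,
               pct_individuals = 100 * mean(part > 0),
               cv_participation = if (mean(part) > 0)
                 stats::sd(part) / mean(part) else NA_real_)
  })
  diag <- do.call(rbind, diag)
  ok <- all(diag$pct_individuals > 50) &
    all(diag$cv_participation < 1, na.rm = TRUE)
  structure(list(bounds = bounds, class = cls, diagnostics = diag,
                 valid = ok,
                 report = if (ok) "diagnostics pass" else
                   paste("scheme rejected: representation or CV criterion",
                         "failed; try fewer classes")),
            class = "distance_classes")
}

#' The Sp statistic
#'
#' \eqn{Sp = -b / (1 - F_{ij(1)})}, the standard quantification of the
#' strength of fine-scale spatial genetic structure, with b the slope of
#' pairwise kinship on log distance and F_ij(1) the mean kinship of the
#' first distance class.
#'
#' @param b regression slope of kinship on ln(distance).
#' @param f1 mean kinship of the first distance class.
#' @export
sp_statistic <- function(b, f1) -b / (1 - f1)

# slope of y on log-distance over usable pairs (vectors already subset)
ln_slope <- function(fv, logd) {
  mx <- mean(logd); my <- mean(fv)
  sum((logd - mx) * (fv - my)) / sum((logd - mx)^2)
}

#' Kinship correlogram with permutation test, jackknife and Sp
#'
#' Computes per-distance-class mean kinship, the regression slope b of
#' pairwise kinship on the natural log of distance over all usable pairs
#' (distance > 0 and non-missing kinship; zero-distance pairs enter class
#' means but not the regression), a one-sided permutation test of b < 0 by
#' permuting whole individuals across spatial positions, a delete-one-locus
#' jackknife mean and SE of b, a 95% permutation envelope per class, and
#' \eqn{Sp = -b/(1 - F_{ij(1)})}.
#'
#' @param k a `kinship_matrix` from [loiselle_kinship()].
#' @param s a `spatial_frame` with ids matching `k`.
#' @param scheme a `distance_classes` scheme (default: 5 quantile classes).
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed (required).
#' @return an object of class `correlogram`: list with `per_class`
#'   (data.frame: class, upper, n_pairs, mean_F, se_F, env_lo, env_hi),
#'   `b`, `b_se`, `b_jack`, `p_slope`, `F1`, `Sp`, `n_zero_excluded`.
#' @export
correlogram <- function(k, s, scheme = NULL, n_perm = 10000, seed) {
  if (missing(seed)) stop("an explicit RNG seed is required")
  stopifnot(identical(k$ids, s$id))
  if (is.null(scheme)) scheme <- build_distance_classes(s, 5)
  d <- pair_distances(s)
  ut <- upper.tri(d)
  fv_all <- k$F[ut]
  dv <- d[ut]
  cls <- scheme$class[ut]
  usable <- !is.na(fv_all)
  if (length(unique(cls[usable])) < 2)
    stop("fewer than 2 usable distance classes")
  reg <- usable & dv > 0
  n_zero <- sum(usable & dv == 0)
  b_obs <- ln_slope(fv_all[reg], log(dv[reg]))
  # class means with jackknife-over-loci SE
  nclass <- length(scheme$bounds)
  mean_F <- vapply(seq_len(nclass), function(cc)
    mean(fv_all[usable & cls == cc]), numeric(1))
  L <- length(k$den)
  jack_class <- matrix(NA_real_, L, nclass)
  jack_b <- numeric(L)
  if (L >= 2) {
    for (l in seq_len(L)) {
      Fl <- kinship_drop_locus(k, l)[ut]
      okl <- !is.na(Fl)
      jack_class[l, ] <- vapply(seq_len(nclass), function(cc)
        mean(Fl[okl & cls == cc]), numeric(1))
      rl <- okl & dv > 0
      jack_b[l] <- ln_slope(Fl[rl], log(dv[rl]))
    }
    se_F <- sqrt((L - 1) / L *
                   colSums(sweep(jack_class, 2, colMeans(jack_class))^2))
    b_jack <- mean(jack_b)
    b_se <- sqrt((L - 1) / L * sum((jack_b - b_jack)^2))
    if (L < 4)
      attr(b_se, "note") <- "jackknife SE from fewer than 4 loci"
  } else {
    se_F <- rep(NA_real_, nclass); b_jack <- b_obs; b_se <- NA_real_
  }
  # permutation: shuffle individuals over spatial positions
  set.seed(seed)
  n <- nrow(d)
  null_b <- numeric(n_perm)
  null_class <- matrix(NA_real_, n_perm, nclass)
  for (p in seq_len(n_perm)) {
    perm <- sample(n)
    dp <- d[perm, perm][ut]
    cp <- scheme$class[perm, perm][ut]
    rp <- usable & dp > 0
    null_b[p] <- ln_slope(fv_all[rp], log(dp[rp]))
    null_class[p, ] <- vapply(seq_len(nclass), function(cc) {
      v <- fv_all[usable & cp == cc]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  p_slope <- (sum(null_b <= b_obs) + 1) / (n_perm + 1)
  env <- apply(null_class, 2, stats::quantile,
               probs = c(0.025, 0.975), na.rm = TRUE)
  F1 <- mean_F[1]
  per_class <- data.frame(
    class = seq_len(nclass), upper = scheme$bounds,
    n_pairs = vapply(seq_len(nclass), function(cc)
      sum(usable & cls == cc), numeric(1)),
    mean_F = mean_F, se_F = se_F, env_lo = env[1, ], env_hi = env[2, ])
  structure(list(per_class = per_class, b = b_obs, b_jack = b_jack,
                 b_se = b_se, p_slope = p_slope, F1 = F1,
                 Sp = sp_statistic(b_obs, F1),
                 n_zero_excluded = n_zero, n_perm = n_perm),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("kinship correlogram:", nrow(x$per_class), "classes\n")
  cat(sprintf("b = %.5f (SE %.5f), one-sided P(b<0) = %.4g\n",
              x$b, x$b_se, x$p_slope))
  cat(sprintf("F1 = %.4f, Sp = %.5f\n", x$F1, x$Sp))
  invisible(x)
}

#' FSGS analysis of haploid plastid haplotypes
#'
#' Runs the kinship correlogram on a maternally inherited haploid marker:
#' single-locus Loiselle kinship with 0/1 dosages, then [correlogram()].
#' With monomorphic haplotypes the analysis is undefined and `NULL` is
#' returned with a message.
#'
#' @inheritParams correlogram
#' @param h a `haplotype_set` with ids matching `s`.
#' @export
plastid_fsgs <- function(h, s, scheme = NULL, n_perm = 10000, seed) {
  hh <- h$haplotype[!is.na(h$haplotype)]
  if (length(unique(hh)) < 2) {
    message("monomorphic haplotypes: plastid FSGS not computed")
    return(NULL)
  }
  k <- loiselle_kinship(h)
  correlogram(k, s, scheme = scheme, n_perm = n_perm, seed = seed)
}
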