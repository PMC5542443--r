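# Diversity, inbreeding, null-allele and clonality statistics.

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of
#' `standard_size` gene copies, by the hypergeometric rarefaction formula
#' \deqn{A_R = \sum_a \left[1 - {N - N_a \choose g} / {N \choose g}\right]}
#' with \eqn{N} gene copies at the locus, \eqn{N_a} copies of allele
#' \eqn{a} and \eqn{g} the standardised sample size. Rarefaction is in gene
#' copies; pass `2 * n_individuals` to standardise on a diploid sample of
#' `n_individuals`.
#'
#' @param g a `genotype_matrix`, or a named vector of allele counts for a
#'   single locus (haploid data, e.g. plastid haplotype counts, may be given
#'   this way).
#' @param standard_size number of gene copies g to rarefy to.
#' @return list with `per_locus` (named numeric) and `mean`.
#' @export
rarefied_allelic_richness <- function(g, standard_size) {
  counts <- if (inherits(g, "genotype_matrix")) {
    lapply(stats::setNames(g$loci, g$loci), function(l) allele_counts(g, l))
  } else list(locus = g)
  ncop <- vapply(counts, sum, numeric(1))
  if (any(standard_size > ncop))
    stop("standard_size ", standard_size, " exceeds the ",
         min(ncop), " gene copies available at locus ",
         names(counts)[which.min(ncop)])
  per <- vapply(counts, function(cts) {
    N <- sum(cts)
    # 1 - C(N - Na, g)/C(N, g) computed on log scale for stability
    sum(1 - exp(lchoose(N - cts, standard_size) - lchoose(N, standard_size)))
  }, numeric(1))
  list(per_locus = per, mean = mean(per))
}

#' Unbiased expected heterozygosity with jackknife-over-loci SE
#'
#' Nei's unbiased gene diversity per locus,
#' \eqn{H_E = n/(n-1)\,(1 - \sum_a p_a^2)} with \eqn{n} the number of gene
#' copies typed, its multilocus mean, and a delete-one-locus jackknife
#' standard error of the mean. With a single locus the SE is `NA`.
#'
#' @param g a `genotype_matrix`, or a named count vector for one haploid
#'   locus (returns the unbiased haplotype diversity `h`).
#' @return list with `per_locus`, `mean`, `se`, `H_O` (observed
#'   heterozygosity per locus, diploid input only).
#' @export
expected_heterozygosity <- function(g) {
  if (!inherits(g, "genotype_matrix")) {
    cts <- g; n <- sum(cts)
    if (n < 2) stop("need at least 2 gene copies")
    he <- n / (n - 1) * (1 - sum((cts / n)^2))
    return(list(per_locus = c(locus = he), mean = he, se = NA_real_,
                H_O = NULL))
  }
  per <- vapply(g$loci, function(l) {
    cts <- allele_counts(g, l); n <- sum(cts)
    if (n < 2) stop("fewer than 2 gene copies at locus ", l)
    n / (n - 1) * (1 - sum((cts / n)^2))
  }, numeric(1))
  ho <- vapply(seq_along(g$loci), function(j) {
    ok <- !is.na(g$a1[, j])
    mean(g$a1[ok, j] != g$a2[ok, j])
  }, numeric(1))
  names(ho) <- g$loci
  L <- length(per)
  se <- if (L < 2) NA_real_ else {
    pseudo <- vapply(seq_len(L), function(j) mean(per[-j]), numeric(1))
    sqrt((L - 1) / L * sum((pseudo - mean(pseudo))^2))
  }
  list(per_locus = per, mean = mean(per), se = se, H_O = ho)
}

# per-locus H_E/H_O components used by F_IS (ratio-of-sums across loci)
fis_components <- function(g) {
  he <- expected_heterozygosity(g)
  data.frame(locus = g$loci, He = he$per_locus, Ho = he$H_O,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fixation index with an allele-permutation test
#'
#' \eqn{F_{IS} = 1 - H_O/H_E} per locus, combined across loci as a ratio of
#' locus-summed components. The null distribution is obtained by randomly
#' re-pairing gene copies within the population at each locus (allele
#' permutation), which preserves allele frequencies but destroys genotypic
#' association. P-values use the (extreme + 1)/(n_perm + 1) convention.
#'
#' @param g a `genotype_matrix`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `per_locus`, `multilocus`, `p_high` (one-tailed,
#'   heterozygote deficit), `p_low`, `p_two`, and `null` (the permuted
#'   multilocus values).
#' @export
fixation_index <- function(g, n_perm = 10000, seed) {
  if (missing(seed)) stop("an explicit RNG seed is required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  comp <- fis_components(g)
  if (all(comp$He == 0)) stop("all loci monomorphic: F_IS undefined")
  per <- ifelse(comp$He > 0, 1 - comp$Ho / comp$He, NA_real_)
  names(per) <- comp$locus
  obs <- 1 - sum(comp$Ho) / sum(comp$He)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    ho <- vapply(seq_along(g$loci), function(j) {
      al <- c(g$a1[, j], g$a2[, j]); al <- al[!is.na(al)]
      al <- sample(al)
      k <- length(al) %/% 2
      mean(al[seq_len(k)] != al[k + seq_len(k)])
    }, numeric(1))
    1 - sum(ho) / sum(comp$He)
  }, numeric(1))
  p_high <- (sum(null >= obs) + 1) / (n_perm + 1)
  p_low <- (sum(null <= obs) + 1) / (n_perm + 1)
  list(per_locus = per, multilocus = obs,
       p_high = p_high, p_low = p_low, p_two = min(1, 2 * min(p_high, p_low)),
       null = null)
}

# ---------------------------------------------------------------------------
# Null alleles
# ---------------------------------------------------------------------------

# EM maximum-likelihood estimate of the null-allele frequency at one locus,
# treating whole-locus amplification failures as candidate null homozygotes
# (the model underlying Brookfield's 1996 second estimator). Latent states:
# an apparent homozygote a/a is truly a/a or a/null; a blank is null/null.
null_freq_em <- function(a1, a2, n_blank = sum(is.na(a1)),
                         max_iter = 500, tol = 1e-10) {
  ok <- !is.na(a1)
  h1 <- a1[ok]; h2 <- a2[ok]
  het <- h1 != h2
  levs <- sort(unique(c(h1, h2)))
  n_ind <- length(h1) + n_blank
  # initial: equal split of observed copies, small r
  cnt <- table(factor(c(h1, h2), levels = levs))
  p <- as.numeric(cnt) / sum(cnt) * 0.95
  names(p) <- levs
  r <- 0.05
  hom_allele <- h1[!het]
  het_tab <- table(factor(c(h1[het], h2[het]), levels = levs))
  for (it in seq_len(max_iter)) {
    # E-step: expected null copies in apparent homozygotes
    pa <- p[hom_allele]
    w_null <- (2 * pa * r) / (pa^2 + 2 * pa * r)   # P(a/null | apparent a/a)
    # expected allele-copy counts
    cnt_a <- as.numeric(het_tab)
    hom_copies <- tapply(2 - w_null, factor(hom_allele, levels = levs), sum)
    hom_copies[is.na(hom_copies)] <- 0
    cnt_a <- cnt_a + as.numeric(hom_copies)
    null_copies <- sum(w_null) + 2 * n_blank
    tot <- sum(cnt_a) + null_copies
    p_new <- cnt_a / tot
    r_new <- null_copies / tot
    if (max(abs(c(p_new - p, r_new - r))) < tol) { p <- p_new; r <- r_new; break }
    p <- p_new; r <- r_new
    names(p) <- levs
  }
  list(r = unname(r), p = stats::setNames(as.numeric(p), levs), n = n_ind)
}

#' Null-allele frequency estimation and corrected fixation index
#'
#' Per locus, the frequency `r` of a non-amplifying (null) allele is
#' estimated by maximum likelihood under the model in which apparent
#' homozygotes may carry one null copy and whole-locus amplification
#' failures are null homozygotes (Brookfield's estimator for data with
#' observable blanks), solved by EM. Loci with an observed heterozygote
#' excess get `r = 0`. The corrected fixation index `F_IS*` is recomputed
#' from the null-adjusted genotype expectations: the expected true
#' heterozygosity includes the null allele as an ordinary allele, and the
#' observed heterozygosity is replaced by its model expectation including
#' visible/null heterozygotes.
#'
#' @param g a `genotype_matrix`.
#' @return list with `per_locus` data.frame (`locus`, `r`, `Fis`,
#'   `Fis_star`) and `multilocus` (`Fis`, `Fis_star` by ratio of sums).
#' @export
null_allele_correction <- function(g) {
  comp <- fis_components(g)
  res <- lapply(seq_along(g$loci), function(j) {
    a1 <- g$a1[, j]; a2 <- g$a2[, j]
    ok <- !is.na(a1)
    if (comp$Ho[j] >= comp$He[j] || sum(ok) == 0)
      return(list(r = 0, He_star = comp$He[j], Ho_star = comp$Ho[j]))
    fit <- null_freq_em(a1, a2)
    # fit$p are true visible-allele frequencies (summing to 1 - r)
    p_all <- c(fit$p, null = fit$r)
    p_all <- p_all / sum(p_all)
    n_cop <- 2 * fit$n
    He_star <- n_cop / (n_cop - 1) * (1 - sum(p_all^2))
    # expected true heterozygosity among sampled individuals: observed hets
    # plus expected a/null fraction of apparent homozygotes
    het <- ok & a1 != a2
    hom_allele <- a1[ok & a1 == a2]
    pa <- fit$p[hom_allele]
    w_null <- (2 * pa * fit$r) / (pa^2 + 2 * pa * fit$r)
    Ho_star <- (sum(het) + sum(w_null)) / fit$n
    list(r = fit$r, He_star = He_star, Ho_star = Ho_star)
  })
  r <- vapply(res, `[[`, numeric(1), "r")
  He_s <- vapply(res, `[[`, numeric(1), "He_star")
  Ho_s <- vapply(res, `[[`, numeric(1), "Ho_star")
  per <- data.frame(
    locus = g$loci, r = r,
    Fis = ifelse(comp$He > 0, 1 - comp$Ho / comp$He, NA_real_),
    Fis_star = ifelse(He_s > 0, 1 - Ho_s / He_s, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_locus = per,
       multilocus = c(Fis = 1 - sum(comp$Ho) / sum(comp$He),
                      Fis_star = 1 - sum(Ho_s) / sum(He_s)))
}

# ---------------------------------------------------------------------------
# Clonality
# ---------------------------------------------------------------------------

#' Clonality analysis: repeated multilocus genotypes and psex
#'
#' For each multilocus genotype observed more than once, computes the
#' genotype probability under Hardy-Weinberg expectations
#' (optionally adjusted by an inbreeding coefficient F following GenClone:
#' \eqn{p_a^2 + F p_a (1-p_a)} for homozygotes, \eqn{2 p_a p_b (1-F)} for
#' heterozygotes) with sample-frequency plug-in allele frequencies, and the
#' probability `psex` that the k observed copies include at least k-1
#' independent sexual repeats of the genotype among the other N-1 sampled
#' individuals (binomial tail on P_gen).
#'
#' @param g a `genotype_matrix`.
#' @param f_correction optional inbreeding coefficient F (default 0).
#' @param clone_threshold psex below which repeats are flagged clones
#'   (default 0.01).
#' @return data.frame with one row per repeated genotype: `genet`, `ramets`,
#'   `ids`, `P_gen`, `psex`, `is_clone`; attribute `"excluded"` lists
#'   individuals dropped for missing data. Zero-row when no repeats.
#' @export
clonality <- function(g, f_correction = 0, clone_threshold = 0.01) {
  complete <- rowSums(is.na(g$a1)) == 0
  if (any(!complete))
    warning(sum(!complete), " individual(s) with missing data excluded ",
            "from clonal analysis")
  ids <- g$ids[complete]
  key <- apply(cbind(
    matrix(paste(pmin(g$a1, g$a2), pmax(g$a1, g$a2), sep = "/"),
           nrow = length(g$ids))[complete, , drop = FALSE]),
    1, paste, collapse = ";")
  N <- length(g$ids)
  freqs <- lapply(stats::setNames(g$loci, g$loci), function(l) {
    cts <- allele_counts(g, l); cts / sum(cts)
  })
  p_gen_of <- function(i) {
    prod(vapply(seq_along(g$loci), function(j) {
      a <- g$a1[complete, , drop = FALSE][i, j]
      b <- g$a2[complete, , drop = FALSE][i, j]
      p <- freqs[[j]]
      if (a == b) p[[a]]^2 + f_correction * p[[a]] * (1 - p[[a]])
      else 2 * p[[a]] * p[[b]] * (1 - f_correction)
    }, numeric(1)))
  }
  tab <- table(key)
  rep_keys <- names(tab[tab > 1])
  if (length(rep_keys) == 0L) {
    out <- data.frame(genet = character(0), ramets = integer(0),
                      ids = character(0), P_gen = numeric(0),
                      psex = numeric(0), is_clone = logical(0))
    attr(out, "excluded") <- g$ids[!complete]
    return(out)
  }
  rows <- lapply(seq_along(rep_keys), function(kk) {
    idx <- which(key == rep_keys[kk])
    pg <- p_gen_of(idx[1])
    k <- length(idx)
    psex <- psex_binomial(pg, N = N, k = k)
    data.frame(genet = paste0("G", kk), ramets = k,
               ids = paste(ids[idx], collapse = ","),
               P_gen = pg, psex = psex,
               is_clone = psex < clone_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- g$ids[!complete]
  out
}

#' Binomial-tail psex
#'
#' Probability of observing at least `k - 1` further independent draws of a
#' genotype with probability `P_gen` among the `N - 1` individuals other
#' than its first occurrence:
#' \eqn{psex = \sum_{j=k-1}^{N-1} {N-1 \choose j} P^j (1-P)^{N-1-j}}.
#'
#' @param p_gen genotype probability.
#' @param N sample size.
#' @param k number of observed copies.
#' @export
psex_binomial <- function(p_gen, N, k) {
  stats::pbinom(k - 2, size = N - 1, prob = p_gen, lower.tail = FALSE)
}

#' Per-population diversity summary
#'
#' Assembles the nuclear and plastid diversity statistics into one row per
#' population in the layout of a standard diversity table: sample sizes,
#' mean allele number A, rarefied allelic richness A_R (with SD across
#' loci), H_E with jackknife SE, F_IS with permutation significance, the
#' null-corrected F_IS*, and for plastid data the haplotype number, rarefied
#' haplotype richness and unbiased haplotype diversity h.
#'
#' @param g a `genotype_matrix` or `NULL`.
#' @param h a `haplotype_set` or `NULL`.
#' @param rarefy_individuals standardised diploid sample size for A_R
#'   (gene copies used = 2x this; default the sample size).
#' @param rarefy_hap standardised sample size for plastid richness
#'   (default 10 individuals).
#' @param n_perm permutations for the F_IS test.
#' @param seed RNG seed.
#' @return one-row data.frame.
#' @export
diversity_summary <- function(g, h = NULL, rarefy_individuals = NULL,
                              rarefy_hap = 10, n_perm = 10000, seed = 1) {
  out <- data.frame(n_nuc = NA_integer_, n_loci = NA_integer_, A = NA_real_,
                    A_R = NA_real_, A_R_sd = NA_real_, H_E = NA_real_,
                    H_E_se = NA_real_, F_IS = NA_real_, F_IS_p = NA_real_,
                    F_IS_star = NA_real_, n_cp = NA_integer_,
                    hap = NA_integer_, A_Rp = NA_real_, hdiv = NA_real_)
  if (!is.null(g)) {
    n <- length(g$ids)
    if (is.null(rarefy_individuals)) {
      gmin <- min(vapply(g$loci, function(l) sum(allele_counts(g, l)),
                         numeric(1)))
      rarefy_individuals <- floor(gmin / 2)
    }
    ar <- rarefied_allelic_richness(g, 2 * rarefy_individuals)
    he <- expected_heterozygosity(g)
    out$n_nuc <- n; out$n_loci <- length(g$loci)
    out$A <- mean(vapply(g$loci, function(l) length(allele_counts(g, l)),
                         numeric(1)))
    out$A_R <- ar$mean; out$A_R_sd <- stats::sd(ar$per_locus)
    out$H_E <- he$mean; out$H_E_se <- he$se
    monomorphic <- all(he$per_locus == 0)
    if (!monomorphic) {
      fis <- fixation_index(g, n_perm = n_perm, seed = seed)
      out$F_IS <- fis$multilocus; out$F_IS_p <- fis$p_two
      out$F_IS_star <- null_allele_correction(g)$multilocus[["Fis_star"]]
    }
  }
  if (!is.null(h)) {
    hh <- h$haplotype[!is.na(h$haplotype)]
    cts <- table(hh)
    out$n_cp <- length(hh); out$hap <- length(cts)
    if (length(hh) >= rarefy_hap)
      out$A_Rp <- rarefied_allelic_richness(cts, rarefy_hap)$mean
    out$hdiv <- if (length(hh) >= 2)
      expected_heterozygosity(cts)$mean else NA_real_
  }
  out
}
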