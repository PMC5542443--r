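# Pipeline orchestration and report builders: per-population summary
# tables in the shapes of the standard diversity / FSGS / gene-pool /
# heterogeneity report tables.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis chain; every stochastic
#' stage receives a seed derived deterministically from `seed`, and the
#' whole configuration is serialised next to the outputs so a run can be
#' reproduced exactly.
#'
#' @param seed master RNG seed.
#' @param n_perm permutations for the kinship/F_IS/F_ST/Mantel tests.
#' @param spca_perm permutations for the G/L tests.
#' @param n_classes number of distance classes.
#' @param k_grid K values for admixture clustering.
#' @param admix_reps replicate chains per K.
#' @param burnin,iters Gibbs sweeps (burn-in / total).
#' @param thresholds ancestry thresholds for gene-pool assignment.
#' @param rarefy_individuals,rarefy_hap rarefaction sample sizes.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(seed, n_perm = 10000, spca_perm = 999, n_classes = 5,
                       k_grid = 1:4, admix_reps = 3,
                       burnin = 20000, iters = 80000,
                       thresholds = c(0.5, 0.875),
                       rarefy_individuals = NULL, rarefy_hap = 10) {
  if (missing(seed)) stop("an explicit master seed is required")
  structure(list(seed = seed, n_perm = n_perm, spca_perm = spca_perm,
                 n_classes = n_classes, k_grid = k_grid,
                 admix_reps = admix_reps, burnin = burnin, iters = iters,
                 thresholds = thresholds,
                 rarefy_individuals = rarefy_individuals,
                 rarefy_hap = rarefy_hap),
            class = "run_config")
}

# deterministic per-stage seeds below 2^31
stage_seed <- function(cfg, stage) {
  (cfg$seed * 1103515245 + match(stage, c("diversity", "fsgs", "plastid",
                                          "spca", "admixture", "fst",
                                          "tests")) * 12345) %% 2147483647
}

#' Run the full within-population analysis pipeline
#'
#' Executes diversity -> FSGS -> sPCA -> admixture -> heterogeneity on one
#' population dataset and assembles the four standard report tables:
#' diversity (sample sizes, A, A_R, H_E, F_IS, F_IS*, plastid richness),
#' FSGS (F1, Sp, b, eig.sPCA, plastid Sp), gene pools (K, F_ST at both
#' thresholds, PI50, PI87) and heterogeneity (ANOVA of sPCA scores on
#' haplotype and altitude classes). Identical configuration and seed give
#' identical outputs.
#'
#' @param dataset a `popgen_dataset` from [join_dataset()] or a
#'   `sim_dataset` from [simulate_population()].
#' @param cfg a [run_config()].
#' @param out_dir optional directory; when given, the tables are written as
#'   TSV (`table_diversity.tsv`, `table_fsgs.tsv`, `table_genepools.tsv`,
#'   `table_heterogeneity.tsv`) with a `manifest.yml` recording the full
#'   configuration and its hash.
#' @return list with `diversity`, `fsgs`, `genepools`, `heterogeneity`
#'   (data.frames) and `detail` (the underlying result objects).
#' @export
run_pipeline <- function(dataset, cfg, out_dir = NULL) {
  g <- dataset$genotypes
  s <- dataset$coords
  h <- dataset$haplotypes
  if (is.null(g) || is.null(s)) stop("dataset lacks genotypes or coordinates")
  detail <- list()

  # diversity ---------------------------------------------------------------
  div <- diversity_summary(g, h, rarefy_individuals = cfg$rarefy_individuals,
                           rarefy_hap = cfg$rarefy_hap,
                           n_perm = cfg$n_perm,
                           seed = stage_seed(cfg, "diversity"))
  detail$clonality <- clonality(g)
  t_div <- cbind(div,
                 F_IS_sig = signif_stars(div$F_IS_p))

  # fsgs ---------------------------------------------------------------------
  scheme <- build_distance_classes(s, cfg$n_classes)
  k <- loiselle_kinship(g)
  cg <- correlogram(k, s, scheme, n_perm = cfg$n_perm,
                    seed = stage_seed(cfg, "fsgs"))
  detail$correlogram <- cg
  pl <- NULL
  if (!is.null(h)) {
    hs <- if (!is.null(dataset$hap_coords)) dataset$hap_coords else s
    hh <- h
    if (!identical(hh$ids, hs$id)) {
      common <- intersect(hh$ids, hs$id)
      hh <- haplotype_set(common, hh$haplotype[match(common, hh$ids)])
      hs <- hs[match(common, hs$id), , drop = FALSE]
      class(hs) <- c("spatial_frame", "data.frame")
    }
    if (length(hh$ids) >= 5)
      pl <- plastid_fsgs(hh, hs, n_perm = cfg$n_perm,
                         seed = stage_seed(cfg, "plastid"))
  }
  detail$plastid <- pl

  # spca ----------------------------------------------------------------------
  net <- build_network(s, "knn", k = min(10, nrow(s) - 1))
  sp <- spca(g, net, s = s)
  gl <- g_l_tests(g, net, n_perm = cfg$spca_perm,
                  seed = stage_seed(cfg, "spca"))
  detail$spca <- sp; detail$gl <- gl
  t_fsgs <- data.frame(
    n_nuc = length(g$ids), n_classes = length(scheme$bounds),
    first_class_m = scheme$bounds[1], F1 = cg$F1, Sp = cg$Sp,
    Sp_sig = signif_stars(cg$p_slope), b = cg$b, b_se = cg$b_se,
    eig_spca = sp$eig_spca, G_sig = signif_stars(gl$p_G),
    L_sig = signif_stars(gl$p_L),
    Sp_plastid = if (is.null(pl)) NA_real_ else pl$Sp,
    b_plastid = if (is.null(pl)) NA_real_ else pl$b)

  # admixture ------------------------------------------------------------------
  runs <- lapply(cfg$k_grid, function(K)
    run_admixture(g, K, burnin = cfg$burnin, iters = cfg$iters,
                  n_reps = cfg$admix_reps,
                  seed = stage_seed(cfg, "admixture") + K))
  ks <- select_k(runs)
  detail$admixture <- runs; detail$k_selection <- ks
  bestK <- ks$best_L
  best <- runs[[match(bestK, cfg$k_grid)]]
  if (bestK >= 2) {
    as50 <- assign_gene_pools(best, cfg$thresholds[1])
    as87 <- assign_gene_pools(best, cfg$thresholds[2])
    fst50 <- try_fst(g, as50$label, cfg)
    fst87 <- try_fst(g, as87$label, cfg)
    t_gp <- data.frame(K = bestK,
                       Fst_50 = fst50$Fst, Fst_50_sig = signif_stars(fst50$p),
                       Fst_87 = fst87$Fst, Fst_87_sig = signif_stars(fst87$p),
                       PI50 = as50$pct_assigned, PI87 = as87$pct_assigned)
  } else {
    t_gp <- data.frame(K = 1L, Fst_50 = NA_real_, Fst_50_sig = "nd",
                       Fst_87 = NA_real_, Fst_87_sig = "nd",
                       PI50 = NA_real_, PI87 = NA_real_)
  }

  # heterogeneity ---------------------------------------------------------------
  score1 <- sp$scores[, 1]
  hap_test <- NULL
  if (!is.null(h) && all(g$ids %in% h$ids)) {
    labs <- h$haplotype[match(g$ids, h$ids)]
    if (length(unique(stats::na.omit(labs))) >= 2)
      hap_test <- tryCatch(anova_scores(score1, labs), error = function(e) NULL)
  }
  alt_test <- NULL
  if (!all(is.na(s$altitude))) {
    ac <- altitude_classes(s)
    if (length(unique(ac$class)) >= 2)
      alt_test <- tryCatch(anova_scores(score1, ac$class),
                           error = function(e) NULL)
  }
  t_het <- data.frame(
    P_hap = if (is.null(hap_test)) NA_real_ else hap_test$p,
    P_hap_sig = if (is.null(hap_test)) "nc" else signif_stars(hap_test$p),
    P_alt = if (is.null(alt_test)) NA_real_ else alt_test$p,
    P_alt_sig = if (is.null(alt_test)) "nc" else signif_stars(alt_test$p))
  detail$hap_anova <- hap_test; detail$alt_anova <- alt_test

  out <- list(diversity = t_div, fsgs = t_fsgs, genepools = t_gp,
              heterogeneity = t_het, detail = detail)
  if (!is.null(out_dir)) write_report(out, cfg, out_dir)
  out
}

try_fst <- function(g, labels, cfg) {
  tryCatch(fst_among_pools(g, labels, n_perm = cfg$n_perm,
                           seed = stage_seed(cfg, "fst")),
           error = function(e) list(Fst = NA_real_, p = NA_real_))
}

write_report <- function(res, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c(diversity = "table_diversity.tsv", fsgs = "table_fsgs.tsv",
            genepools = "table_genepools.tsv",
            heterogeneity = "table_heterogeneity.tsv")
  for (nm in names(tabs))
    utils::write.table(res[[nm]], file.path(out_dir, tabs[nm]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_plain <- unclass(cfg)
  tmp <- tempfile(); yaml::write_yaml(cfg_plain, tmp)
  manifest <- list(config = cfg_plain,
                   config_hash = unname(tools::md5sum(tmp)),
                   package_version = as.character(
                     utils::packageVersion("finekin")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  unlink(tmp)
  invisible(out_dir)
}
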