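# Published per-population summary statistics for the seven Symphonia
# globulifera populations (four Neotropical, three African). These printed
# values are inputs for the cross-population arithmetic: the Sp identity,
# the continental contrasts and the altitude correlation.

#' Published FSGS summary statistics for Symphonia globulifera
#'
#' Per-population fine-scale spatial genetic structure estimates from the
#' published study of seven S. globulifera populations: sample size, number
#' of distance classes, upper bound of the first class (m), mean first-class
#' kinship F_ij(1), the jackknife mean regression slope b of kinship on log
#' distance with its SE, the printed Sp, and the first sPCA eigenvalue.
#'
#' @return data.frame with one row per population, columns `population`,
#'   `continent`, `n_nuc`, `n_classes`, `first_class_m`, `F1`, `Sp`, `b`,
#'   `b_se`, `eig_spca`.
#' @export
symphonia_fsgs <- function() {
  data.frame(
    population = c("BCI", "Yasuni", "Paracou", "Itubera",
                   "SaoTome", "NkongMekak", "Mbikiliki"),
    continent = c(rep("Neotropics", 4), rep("Africa", 3)),
    n_nuc = c(147L, 34L, 148L, 85L, 42L, 70L, 94L),
    n_classes = c(7L, 6L, 4L, 5L, 6L, 5L, 7L),
    first_class_m = c(113, 131, 203, 152, 856, 312, 240),
    F1 = c(0.030, 0.003, 0.015, 0.009, 0.084, 0.020, 0.072),
    Sp = c(0.0166, 0.0003, 0.0090, 0.0074, 0.0341, 0.0124, 0.0273),
    b = c(-0.0161, -0.0003, -0.0088, -0.0074, -0.0312, -0.0122, -0.0253),
    b_se = c(0.0060, 0.0057, 0.0029, 0.0023, 0.0096, 0.0034, 0.0105),
    eig_spca = c(0.029, 0.057, 0.038, 0.073, 0.272, 0.111, 0.154),
    stringsAsFactors = FALSE)
}

#' Published site characteristics for Symphonia globulifera populations
#'
#' Physical characteristics of the seven sampled populations, notably the
#' minimum and maximum sampling altitude (m) whose range drives the
#' altitude-FSGS correlation.
#'
#' @return data.frame with `population`, `continent`, `alt_min`, `alt_max`
#'   and the derived `alt_range`.
#' @export
symphonia_sites <- function() {
  out <- data.frame(
    population = c("BCI", "Yasuni", "Paracou", "Itubera",
                   "SaoTome", "NkongMekak", "Mbikiliki"),
    continent = c(rep("Neotropics", 4), rep("Africa", 3)),
    alt_min = c(149, 231, 38, 92, 671, 473, 467),
    alt_max = c(196, 273, 67, 164, 1896, 838, 911),
    stringsAsFactors = FALSE)
  out$alt_range <- out$alt_max - out$alt_min
  out
}

#' Significance stars
#' @param p a P-value (vectorised).
#' @return `"***"` for P<=0.001, `"**"` for P<=0.01, `"*"` for P<=0.05,
#'   else `"ns"`.
#' @export
signif_stars <- function(p) {
  ifelse(is.na(p), "nc",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns"))))
}
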