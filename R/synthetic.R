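# Forward-in-time, spatially explicit simulator for plant populations on a
# toroidal lattice: one individual per node, mothers chosen through a
# discretised Gaussian seed kernel, fathers through a pollen kernel from
# the mother, maternal plastid inheritance, stepwise SSR mutation.

#' Simulation configuration
#'
#' Defines the habitat, dispersal kernels and marker model of the forward
#' simulator. The population lives on a regular lattice (one reproducing
#' adult per node), so the effective density is exactly
#' `1 / spacing^2` individuals per square metre, which keeps the
#' Wright-neighbourhood anchor \eqn{Sp \approx 1/(4 \pi D \sigma_g^2)}
#' (with \eqn{\sigma_g^2 = \sigma_{seed}^2 + \sigma_{pollen}^2 / 2})
#' interpretable. Kernels are axial Gaussians; generations are
#' non-overlapping; the habitat is toroidal to avoid edge effects.
#'
#' @param nx,ny lattice dimensions (ny = 1 gives a 1-D transect).
#' @param spacing node spacing in metres.
#' @param generations forward generations; default
#'   `ceiling(10 * nx * spacing / sigma_g)` as an equilibration heuristic
#'   (approach to drift-dispersal equilibrium at the sampled scale).
#' @param sigma_seed,sigma_pollen axial kernel SDs in metres.
#' @param selfing selfing rate.
#' @param clonal probability an offspring is a clonal copy of its mother.
#' @param n_loci number of SSR loci.
#' @param mu stepwise mutation rate per copy per generation (40-state
#'   ladder, emulating 3-35 alleles per locus).
#' @param n_hap number of possible plastid haplotype states.
#' @param mu_hap plastid mutation rate (to a random other state).
#' @param null_r per-locus null-allele masking rate (scalar or length
#'   `n_loci`).
#' @param scenario `"panmixia"`, `"ibd"`, `"two_deme_contact"` or
#'   `"altitudinal_barrier"`. Panmixia replaces both kernels by uniform
#'   redistribution over the habitat.
#' @param barrier_permeability probability a dispersal event may cross the
#'   mid-habitat barrier (two-deme and altitudinal scenarios).
#' @param deme_fst founder differentiation between the two demes
#'   (correlated-frequencies draw) for `two_deme_contact`.
#' @param assortative probability that a father is redrawn until he shares
#'   the mother's maternal-line deme (`two_deme_contact`).
#' @param altitude_range `c(min, max)` metres; altitude increases linearly
#'   with x (used by altitude classes and the altitudinal barrier).
#' @param seed RNG seed (required; fixing it fixes the whole dataset).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(nx = 40, ny = 40, spacing = 1, generations = NULL,
                       sigma_seed = 1.8, sigma_pollen = 3.07,
                       selfing = 0, clonal = 0,
                       n_loci = 5, mu = 1e-3, n_hap = 10, mu_hap = 2e-4,
                       null_r = 0, scenario = c("ibd", "panmixia",
                                                "two_deme_contact",
                                                "altitudinal_barrier"),
                       barrier_permeability = 1, deme_fst = 0,
                       assortative = 0, altitude_range = c(0, 100),
                       seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("an explicit RNG seed is required")
  stopifnot(sigma_seed >= 0, sigma_pollen >= 0,
            selfing >= 0, selfing <= 1, clonal >= 0, clonal <= 1,
            mu >= 0, mu <= 1, all(null_r >= 0), all(null_r <= 1),
            barrier_permeability >= 0, barrier_permeability <= 1)
  sigma_g <- sqrt(sigma_seed^2 + sigma_pollen^2 / 2)
  if (is.null(generations))
    generations <- ceiling(10 * nx * spacing / max(sigma_g, spacing))
  structure(list(nx = nx, ny = ny, spacing = spacing,
                 generations = generations,
                 sigma_seed = sigma_seed, sigma_pollen = sigma_pollen,
                 sigma_g = sigma_g, selfing = selfing, clonal = clonal,
                 n_loci = n_loci, mu = mu, n_hap = n_hap, mu_hap = mu_hap,
                 null_r = rep_len(null_r, n_loci), scenario = scenario,
                 barrier_permeability = barrier_permeability,
                 deme_fst = deme_fst, assortative = assortative,
                 altitude_range = altitude_range, seed = seed),
            class = "sim_config")
}

N_STATES <- 40L  # stepwise-mutation ladder size

# torus-wrapped parent node index from Gaussian axial displacements;
# with a semi-permeable barrier at mid-x, blocked crossings are redrawn
# (up to 20 tries) and finally reflected to the same side
draw_parent <- function(col, row, sigma, cfg, blocked) {
  n <- length(col)
  if (cfg$scenario == "panmixia") {
    return(cbind(sample.int(cfg$nx, n, replace = TRUE),
                 sample.int(cfg$ny, n, replace = TRUE)))
  }
  dx <- round(stats::rnorm(n, 0, sigma / cfg$spacing))
  dy <- round(stats::rnorm(n, 0, sigma / cfg$spacing))
  pc <- (col - 1L + dx) %% cfg$nx + 1L
  pr <- (row - 1L + dy) %% cfg$ny + 1L
  if (blocked) {
    half <- cfg$nx / 2
    cross <- ((col <= half) != (pc <= half))
    deny <- cross & (stats::runif(n) > cfg$barrier_permeability)
    tries <- 0L
    while (any(deny) && tries < 20L) {
      m <- sum(deny)
      dx <- round(stats::rnorm(m, 0, sigma / cfg$spacing))
      dy <- round(stats::rnorm(m, 0, sigma / cfg$spacing))
      pc[deny] <- (col[deny] - 1L + dx) %% cfg$nx + 1L
      pr[deny] <- (row[deny] - 1L + dy) %% cfg$ny + 1L
      cross <- ((col[deny] <= half) != (pc[deny] <= half))
      deny[deny] <- cross & (stats::runif(m) > cfg$barrier_permeability)
      tries <- tries + 1L
    }
    stay <- which(deny)
    pc[stay] <- col[stay]; pr[stay] <- row[stay]
  }
  cbind(pc, pr)
}

# stepwise mutation on the 1..N_STATES ladder
mutate_ssr <- function(al, mu) {
  hit <- stats::runif(length(al)) < mu
  if (any(hit)) {
    step <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
    al[hit] <- pmin(pmax(al[hit] + step, 1L), N_STATES)
  }
  al
}

#' Run the forward spatial simulation
#'
#' Non-overlapping generations on a toroidal lattice. Each node's new
#' occupant draws its mother through the seed kernel, then (unless cloned)
#' a father through the pollen kernel centred on the mother (or selfs);
#' nuclear alleles are transmitted Mendelian with stepwise mutation, and
#' the plastid haplotype is the mother's barring mutation. Under
#' `two_deme_contact` the founders form two differentiated gene pools with
#' deme-specific haplotype sets and optional assortative mating; under
#' `altitudinal_barrier` dispersal across the mid-habitat contour is
#' multiplied by the permeability.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_dataset`: list with `genotypes`
#'   (a `genotype_matrix` after null-allele masking), `coords`
#'   (`spatial_frame` with altitude), `haplotypes` (`haplotype_set`),
#'   and `truth` (list: `deme` maternal-line origin, `sigma_seed`,
#'   `sigma_pollen`, `sigma_g`, `density`, `masked` logical array of
#'   null-masked gene copies, `genotypes_true` the unmasked matrix).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$generations >= 1)
  set.seed(cfg$seed)
  N <- cfg$nx * cfg$ny
  col <- rep(seq_len(cfg$nx), times = cfg$ny)
  row <- rep(seq_len(cfg$ny), each = cfg$nx)
  blocked <- cfg$scenario %in% c("two_deme_contact", "altitudinal_barrier") &&
    cfg$barrier_permeability < 1
  half <- cfg$nx / 2
  deme <- ifelse(col <= half, 1L, 2L)

  # founders
  L <- cfg$n_loci
  if (cfg$scenario == "two_deme_contact" && cfg$deme_fst > 0) {
    Fst <- cfg$deme_fst
    A1 <- matrix(0L, N, L); A2 <- matrix(0L, N, L)
    for (j in seq_len(L)) {
      pbar <- as.numeric(stats::rgamma(N_STATES, 1)); pbar <- pbar / sum(pbar)
      conc <- pbar * (1 - Fst) / Fst
      for (dm in 1:2) {
        pd <- stats::rgamma(N_STATES, shape = conc)
        pd <- pd / sum(pd)
        idx <- which(deme == dm)
        A1[idx, j] <- sample.int(N_STATES, length(idx), TRUE, prob = pd)
        A2[idx, j] <- sample.int(N_STATES, length(idx), TRUE, prob = pd)
      }
    }
    # deme-specific haplotype sets (disjoint halves of the state space)
    hap <- ifelse(deme == 1L,
                  sample.int(max(cfg$n_hap %/% 2, 1), N, TRUE),
                  max(cfg$n_hap %/% 2, 1) +
                    sample.int(max(cfg$n_hap - cfg$n_hap %/% 2, 1), N, TRUE))
  } else {
    A1 <- matrix(sample.int(N_STATES, N * L, TRUE), N, L)
    A2 <- matrix(sample.int(N_STATES, N * L, TRUE), N, L)
    hap <- sample.int(cfg$n_hap, N, TRUE)
  }

  node_of <- function(pc) (pc[, 2] - 1L) * cfg$nx + pc[, 1]
  for (gen in seq_len(cfg$generations)) {
    mother <- node_of(draw_parent(col, row, cfg$sigma_seed, cfg, blocked))
    cloned <- stats::runif(N) < cfg$clonal
    father <- node_of(draw_parent(col[mother], row[mother],
                                  cfg$sigma_pollen, cfg, blocked))
    selfed <- stats::runif(N) < cfg$selfing
    father[selfed] <- mother[selfed]
    if (cfg$assortative > 0) {
      want <- stats::runif(N) < cfg$assortative
      bad <- which(want & deme[father] != deme[mother])
      tries <- 0L
      while (length(bad) && tries < 20L) {
        father[bad] <- node_of(draw_parent(col[mother[bad]], row[mother[bad]],
                                           cfg$sigma_pollen, cfg, blocked))
        bad <- bad[deme[father[bad]] != deme[mother[bad]]]
        tries <- tries + 1L
      }
    }
    fromM <- matrix(stats::runif(N * L) < 0.5, N, L)
    fromF <- matrix(stats::runif(N * L) < 0.5, N, L)
    newA1 <- ifelse(fromM, A1[mother, ], A2[mother, ])
    newA2 <- ifelse(fromF, A1[father, ], A2[father, ])
    newA1 <- matrix(mutate_ssr(newA1, cfg$mu), N, L)
    newA2 <- matrix(mutate_ssr(newA2, cfg$mu), N, L)
    # clones copy the mother's genotype unchanged
    if (any(cloned)) {
      newA1[cloned, ] <- A1[mother[cloned], ]
      newA2[cloned, ] <- A2[mother[cloned], ]
    }
    newHap <- hap[mother]
    hmut <- which(stats::runif(N) < cfg$mu_hap & !cloned)
    if (length(hmut))
      newHap[hmut] <- sample.int(cfg$n_hap, length(hmut), TRUE)
    A1 <- newA1; A2 <- newA2; hap <- newHap
    deme <- deme[mother]
  }

  ids <- sprintf("ind%04d", seq_len(N))
  x <- (col - 0.5) * cfg$spacing
  y <- (row - 0.5) * cfg$spacing
  alt <- cfg$altitude_range[1] +
    (x - min(x)) / max(diff(range(x)), 1) * diff(cfg$altitude_range)
  coords <- spatial_frame(ids, x, y, altitude = alt,
                          population = cfg$scenario)
  loci <- sprintf("ssr%02d", seq_len(L))
  g_true <- genotype_matrix(ids, loci, matrix(as.character(A1), N, L),
                            matrix(as.character(A2), N, L))
  # null-allele masking: each gene copy fails independently at rate r[l]
  masked <- array(FALSE, c(N, L, 2))
  a1c <- matrix(as.character(A1), N, L); a2c <- matrix(as.character(A2), N, L)
  for (j in seq_len(L)) {
    r <- cfg$null_r[j]
    if (r <= 0) next
    m1 <- stats::runif(N) < r; m2 <- stats::runif(N) < r
    masked[, j, 1] <- m1; masked[, j, 2] <- m2
    both <- m1 & m2
    a1c[both, j] <- NA; a2c[both, j] <- NA
    only1 <- m1 & !m2
    a1c[only1, j] <- a2c[only1, j]       # appears homozygous for the visible
    only2 <- m2 & !m1
    a2c[only2, j] <- a1c[only2, j]
  }
  g_obs <- genotype_matrix(ids, loci, a1c, a2c)
  structure(list(
    genotypes = g_obs, coords = coords,
    haplotypes = haplotype_set(ids, paste0("H", hap)),
    truth = list(deme = deme, sigma_seed = cfg$sigma_seed,
                 sigma_pollen = cfg$sigma_pollen, sigma_g = cfg$sigma_g,
                 density = 1 / cfg$spacing^2, masked = masked,
                 genotypes_true = g_true),
    config = cfg), class = "sim_dataset")
}

#' Subsample a simulated dataset
#'
#' `design = "random"` draws n individuals uniformly; `design = "transect"`
#' takes the n individuals closest to the habitat's horizontal midline,
#' giving an elongated transect-like geometry.
#'
#' @param d a `sim_dataset`.
#' @param n subsample size.
#' @param design `"random"` or `"transect"`.
#' @param seed RNG seed for the random design.
#' @return a `sim_dataset` restricted to the subsample.
#' @export
sample_transect <- function(d, n, design = c("random", "transect"), seed = 1) {
  design <- match.arg(design)
  N <- length(d$genotypes$ids)
  if (n > N) stop("subsample larger than the population")
  if (design == "random") {
    set.seed(seed)
    keep <- sort(sample.int(N, n))
  } else {
    mid <- mean(range(d$coords$y))
    keep <- sort(order(abs(d$coords$y - mid), d$coords$x)[seq_len(n)])
  }
  coords <- d$coords[keep, , drop = FALSE]
  class(coords) <- c("spatial_frame", "data.frame")
  structure(list(
    genotypes = subset_genotypes(d$genotypes, keep),
    coords = coords,
    haplotypes = haplotype_set(d$haplotypes$ids[keep],
                               d$haplotypes$haplotype[keep]),
    truth = list(deme = d$truth$deme[keep],
                 sigma_seed = d$truth$sigma_seed,
                 sigma_pollen = d$truth$sigma_pollen,
                 sigma_g = d$truth$sigma_g, density = d$truth$density,
                 masked = d$truth$masked[keep, , , drop = FALSE],
                 genotypes_true = subset_genotypes(d$truth$genotypes_true,
                                                   keep)),
    config = d$config), class = "sim_dataset")
}
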