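#' finekin: fine-scale spatial genetic structure of plant populations
#'
#' Tools for within-population spatial population genetics on georeferenced
#' diploid microsatellite (SSR) genotypes and maternally inherited plastid
#' haplotypes: kinship correlograms and the Sp statistic, spatial PCA with
#' Monte-Carlo tests, Bayesian admixture clustering, diversity/inbreeding/
#' clonality statistics, cyto-nuclear and habitat association tests, and a
#' forward-in-time spatial simulator for generating synthetic datasets.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# GenotypeMatrix
# ---------------------------------------------------------------------------

#' Construct a diploid multilocus genotype matrix
#'
#' The central container for co-dominant (SSR) genotypes: an ordered set of
#' individuals typed at one or more loci, each non-missing call being an
#' unordered pair of allele labels. Allele labels are arbitrary strings
#' (typically integer repeat sizes) and are preserved verbatim.
#'
#' @param ids character vector of unique individual identifiers.
#' @param loci character vector of locus names.
#' @param a1,a2 character matrices (individuals x loci) holding the two
#'   allele labels of each call; both `NA` at a missing call.
#' @return an object of class `genotype_matrix` with elements `ids`, `loci`,
#'   `a1`, `a2`.
#' @export
genotype_matrix <- function(ids, loci, a1, a2) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  if (anyDuplicated(ids)) stop("duplicated individual ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) < 2L) stop("need at least 2 individuals")
  if (length(loci) < 1L) stop("need at least 1 locus")
  a1 <- matrix(as.character(a1), nrow = length(ids), ncol = length(loci),
               dimnames = list(ids, loci))
  a2 <- matrix(as.character(a2), nrow = length(ids), ncol = length(loci),
               dimnames = list(ids, loci))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("half-missing calls (one allele NA) at ",
                      sum(half), " cell(s); code the whole call as missing")
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x",
      length(x$loci), "loci\n")
  miss <- round(100 * colMeans(is.na(x$a1)), 1)
  cat("loci:", paste0(x$loci, " (", miss, "% missing)", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$ids), length(x$loci))

#' Subset a genotype matrix by individuals and/or loci
#' @param x a `genotype_matrix`.
#' @param individuals,loci index or name vectors; `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  i <- if (is.null(individuals)) seq_along(x$ids) else individuals
  j <- if (is.null(loci)) seq_along(x$loci) else loci
  genotype_matrix(x$ids[i], x$loci[j],
                  x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE])
}

# Per-locus allele counts as a named integer vector (gene copies per label).
# Internal workhorse for the diversity statistics.
allele_counts <- function(g, locus) {
  al <- c(g$a1[, locus], g$a2[, locus])
  table(al[!is.na(al)])
}

# Dosage matrix: individuals x allele columns, entries in {0, .5, 1} (the
# within-individual frequency of each allele), NA where the locus is missing.
# Columns named "<locus>.<allele>". Used by kinship, sPCA and F_ST.
dosage_matrix <- function(g) {
  blocks <- lapply(seq_along(g$loci), function(j) {
    al1 <- g$a1[, j]; al2 <- g$a2[, j]
    levs <- sort(unique(c(al1, al2)), na.last = NA)
    if (length(levs) == 0L) return(NULL)
    m1 <- outer(al1, levs, `==`)
    m2 <- outer(al2, levs, `==`)
    m <- (m1 + m2) / 2
    dimnames(m) <- list(g$ids, paste0(g$loci[j], ".", levs))
    m[is.na(al1), ] <- NA
    m
  })
  locus_of <- rep(seq_along(g$loci), vapply(blocks, function(b)
    if (is.null(b)) 0L else ncol(b), integer(1)))
  list(X = do.call(cbind, blocks), locus = locus_of)
}

# ---------------------------------------------------------------------------
# SpatialFrame
# ---------------------------------------------------------------------------

#' Construct a spatial frame of individual coordinates and site metadata
#'
#' @param ids individual identifiers (matching a genotype matrix after an
#'   explicit [join_dataset()] step).
#' @param x,y planar coordinates in metres (see `lonlat`). Duplicated
#'   coordinates are allowed (clonal ramets).
#' @param altitude optional altitude in metres.
#' @param morphotype optional categorical label.
#' @param population categorical population label (recycled if length 1).
#' @param lonlat if `TRUE`, `x`/`y` are longitude/latitude in degrees and are
#'   projected to local planar metres by an equirectangular projection about
#'   the population centroid (adequate for extents up to a few km).
#' @return an object of class `spatial_frame` (a data.frame with columns
#'   `id`, `x`, `y`, `altitude`, `morphotype`, `population`).
#' @export
spatial_frame <- function(ids, x, y, altitude = NULL, morphotype = NULL,
                          population = "pop", lonlat = FALSE) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated ids in spatial frame")
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  if (lonlat) {
    R <- 6371008.8
    lat0 <- mean(y) * pi / 180
    xm <- (x - mean(x)) * pi / 180 * R * cos(lat0)
    ym <- (y - mean(y)) * pi / 180 * R
    x <- xm; y <- ym
  }
  out <- data.frame(
    id = ids, x = x, y = y,
    altitude = if (is.null(altitude)) NA_real_ else as.numeric(altitude),
    morphotype = if (is.null(morphotype)) NA_character_ else as.character(morphotype),
    population = rep_len(as.character(population), length(ids)),
    stringsAsFactors = FALSE)
  class(out) <- c("spatial_frame", "data.frame")
  out
}

#' Pairwise Euclidean distances of a spatial frame
#' @param s a `spatial_frame`.
#' @return a symmetric matrix of distances in metres.
#' @export
pair_distances <- function(s) {
  d <- as.matrix(stats::dist(cbind(s$x, s$y)))
  dimnames(d) <- list(s$id, s$id)
  d
}

#' Cut altitudes into classes
#'
#' Default boundaries are the terciles of the observed altitudes (three
#' classes); the original analyses used ad hoc class limits, so explicit
#' `breaks` can be supplied instead.
#'
#' @param s a `spatial_frame` with non-missing `altitude`.
#' @param breaks optional numeric vector of interior cut points (2 cut points
#'   give 3 classes); default = terciles.
#' @return an object of class `altitude_classes`: list with `breaks` (the
#'   full boundary vector covering the observed range) and `class`, an
#'   integer class index per individual.
#' @export
altitude_classes <- function(s, breaks = NULL) {
  alt <- s$altitude
  if (all(is.na(alt))) stop("no altitude data")
  if (is.null(breaks))
    breaks <- stats::quantile(alt, c(1/3, 2/3), na.rm = TRUE, names = FALSE)
  lo <- min(alt, na.rm = TRUE); hi <- max(alt, na.rm = TRUE)
  bounds <- c(lo - 1e-9, sort(breaks), hi)
  cls <- cut(alt, bounds, labels = FALSE, include.lowest = TRUE)
  structure(list(breaks = bounds, class = cls, ids = s$id),
            class = "altitude_classes")
}

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

#' Read diploid genotypes from a delimited table
#'
#' One row per individual. Loci may be coded as two columns per locus
#' (`format = "two_col"`, columns `<locus>` and `<locus>` suffixed pairs
#' named in `loci`) or as one column per locus with both alleles joined by
#' `allele_sep` (`format = "single_col"`). Alleles are kept verbatim as
#' labels. A call equal to the missing token (on either allele) is missing.
#'
#' @param path delimited text file.
#' @param id_col name of the identifier column.
#' @param loci character vector of locus names. For `two_col`, columns
#'   `paste0(locus, c(suffixes))` must exist; for `single_col`, column
#'   `locus` must exist.
#' @param format `"single_col"` or `"two_col"`.
#' @param allele_sep separator inside single-column calls (default "/").
#' @param suffixes the two column suffixes in `two_col` format.
#' @param missing missing-allele token (default `"0"`).
#' @param sep field separator passed to [utils::read.table()].
#' @return a `genotype_matrix` with attribute `"report"`: a list with
#'   `n_individuals`, `n_loci` and `missing_pct` per locus.
#' @export
read_genotypes <- function(path, id_col = "id", loci, format = c("single_col", "two_col"),
                           allele_sep = "/", suffixes = c("_1", "_2"),
                           missing = "0", sep = "\t") {
  format <- match.arg(format)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           fill = FALSE, strip.white = TRUE)
  if (!id_col %in% names(tab)) stop("id column '", id_col, "' not found")
  ids <- tab[[id_col]]
  if (anyDuplicated(ids))
    stop("duplicated individual id: ", ids[duplicated(ids)][1])
  n <- length(ids); L <- length(loci)
  a1 <- matrix(NA_character_, n, L); a2 <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    if (format == "single_col") {
      col <- tab[[loci[j]]]
      if (is.null(col)) stop("locus column '", loci[j], "' not found")
      parts <- strsplit(col, allele_sep, fixed = TRUE)
      bad <- which(lengths(parts) != 2L)
      if (length(bad))
        stop("row ", bad[1], " (id ", ids[bad[1]], "): call '", col[bad[1]],
             "' at locus ", loci[j], " is not two '", allele_sep,
             "'-separated alleles")
      a1[, j] <- vapply(parts, `[`, "", 1L)
      a2[, j] <- vapply(parts, `[`, "", 2L)
    } else {
      c1 <- tab[[paste0(loci[j], suffixes[1])]]
      c2 <- tab[[paste0(loci[j], suffixes[2])]]
      if (is.null(c1) || is.null(c2))
        stop("columns for locus '", loci[j], "' not found")
      a1[, j] <- c1; a2[, j] <- c2
    }
  }
  miss <- a1 == missing | a2 == missing | is.na(a1) | is.na(a2) |
    a1 == "" | a2 == ""
  a1[miss] <- NA; a2[miss] <- NA
  g <- genotype_matrix(ids, loci, a1, a2)
  attr(g, "report") <- list(
    n_individuals = n, n_loci = L,
    missing_pct = stats::setNames(100 * colMeans(miss), loci))
  g
}

#' Write genotypes in the canonical single-column dialect
#'
#' The canonical dialect is tab-separated, one `a/b` column per locus,
#' missing coded `0/0`; [read_genotypes()] on the result round-trips.
#'
#' @param g a `genotype_matrix`.
#' @param path output file.
#' @param missing missing token.
#' @export
write_genotypes <- function(g, path, missing = "0") {
  cells <- matrix(paste0(ifelse(is.na(g$a1), missing, g$a1), "/",
                         ifelse(is.na(g$a2), missing, g$a2)),
                  nrow = length(g$ids))
  out <- data.frame(id = g$ids, cells, stringsAsFactors = FALSE)
  names(out) <- c("id", g$loci)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Haplotype calling from aligned sequences
# ---------------------------------------------------------------------------

#' Call plastid haplotypes from an aligned FASTA
#'
#' Haplotypes are defined by combining three kinds of characters from the
#' alignment: nucleotide substitutions (variable non-gap columns), indels
#' (each distinct gap run, i.e. maximal stretch of `-` with a given start and
#' end, coded as a single presence/absence character regardless of length),
#' and inversions (user-declared column intervals whose gap-free content is
#' scored as forward or reverse-complement relative to the first sequence).
#' Labels `H1, H2, ...` are assigned by first occurrence, so shuffling the
#' input order changes labels only by a consistent relabelling.
#'
#' @param alignment path to an aligned FASTA file, or a named character
#'   vector of equal-length aligned sequences.
#' @param inversion_regions optional list of integer vectors
#'   `c(start, end)` of alignment columns to score for orientation.
#' @return an object of class `haplotype_set`: list with `ids`, `haplotype`
#'   (label per individual), and `characters` (the coded character table).
#' @export
call_haplotypes <- function(alignment, inversion_regions = NULL) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    ss <- Biostrings::readDNAStringSet(alignment)
    seqs <- stats::setNames(as.character(ss), names(ss))
  } else {
    seqs <- stats::setNames(as.character(alignment), names(alignment))
  }
  seqs[] <- toupper(seqs)   # toupper() drops names; keep them
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ","))
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat); L <- ncol(mat)

  inv_cols <- integer(0)
  inv_states <- NULL
  if (!is.null(inversion_regions)) {
    inv_states <- sapply(inversion_regions, function(iv) {
      cols <- iv[1]:iv[2]
      ref <- paste0(mat[1, cols][mat[1, cols] != "-"], collapse = "")
      vapply(seq_len(n), function(i) {
        s <- paste0(mat[i, cols][mat[i, cols] != "-"], collapse = "")
        if (s == ref) "F"
        else if (s == revcomp_chr(ref)) "R"
        else paste0("S:", s)   # divergent content, treated as its own state
      }, "")
    })
    inv_states <- matrix(inv_states, nrow = n)
    inv_cols <- unlist(lapply(inversion_regions, function(iv) iv[1]:iv[2]))
  }

  # gap runs: one character per distinct (start, end) extent
  runs <- lapply(seq_len(n), function(i) {
    r <- rle(mat[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(character(0))
    paste0(starts[keep], "-", ends[keep])
  })
  all_runs <- sort(unique(unlist(runs)))
  gap_chars <- matrix(0L, n, length(all_runs))
  for (i in seq_len(n)) gap_chars[i, ] <- as.integer(all_runs %in% runs[[i]])

  # substitution columns: variable among non-gap states, outside inversions
  scan_cols <- setdiff(seq_len(L), inv_cols)
  is_sub <- vapply(scan_cols, function(j) {
    v <- mat[, j]; v <- v[v != "-"]
    length(unique(v)) > 1L
  }, logical(1))
  sub_cols <- scan_cols[is_sub]
  sub_chars <- mat[, sub_cols, drop = FALSE]

  key <- apply(cbind(sub_chars,
                     if (length(all_runs)) gap_chars else NULL,
                     inv_states), 1, paste, collapse = "|")
  if (length(key) == 0L) key <- rep("", n)   # no variable characters at all
  structure(list(ids = names(seqs),
                 haplotype = paste0("H", match(key, unique(key))),
                 characters = data.frame(
                   id = names(seqs), key = key, stringsAsFactors = FALSE),
                 variant_columns = sub_cols),
            class = "haplotype_set")
}

#' Construct a haplotype set from pre-called labels
#' @param ids individual identifiers.
#' @param haplotype one haplotype label per individual (`NA` allowed).
#' @return a `haplotype_set`.
#' @export
haplotype_set <- function(ids, haplotype) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated ids")
  if (length(haplotype) != length(ids)) stop("length mismatch")
  structure(list(ids = ids, haplotype = as.character(haplotype)),
            class = "haplotype_set")
}

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# ---------------------------------------------------------------------------
# Joining
# ---------------------------------------------------------------------------

#' Join genotypes, coordinates and haplotypes into one dataset
#'
#' Inner-join on individual ids between the genotype matrix and the spatial
#' frame; a haplotype set may cover a different (even disjoint) sample, in
#' which case the plastid component is kept as a separate sub-dataset
#' aligned with whatever coordinates are available for its ids.
#'
#' @param g a `genotype_matrix` (or `NULL` for plastid-only datasets).
#' @param s a `spatial_frame`.
#' @param h optional `haplotype_set`.
#' @return an object of class `popgen_dataset`: list with `genotypes`,
#'   `coords` (spatial frame aligned with the genotypes), `haplotypes`,
#'   `hap_coords` (spatial frame aligned with the haplotyped ids), and
#'   `dropped` (ids present on one side only).
#' @export
join_dataset <- function(g, s, h = NULL) {
  dropped <- list()
  genotypes <- NULL; coords <- NULL
  if (!is.null(g)) {
    common <- intersect(g$ids, s$id)
    if (length(common) == 0L && is.null(h))
      stop("no ids shared between genotypes and coordinates")
    dropped$genotype_only <- setdiff(g$ids, common)
    dropped$coords_only <- setdiff(s$id, union(common, if (is.null(h)) NULL else h$ids))
    if (length(dropped$genotype_only))
      warning(length(dropped$genotype_only),
              " genotyped id(s) without coordinates dropped")
    if (length(common) >= 2L) {
      genotypes <- subset_genotypes(g, match(common, g$ids))
      coords <- s[match(common, s$id), , drop = FALSE]
      class(coords) <- c("spatial_frame", "data.frame")
    }
  }
  haplotypes <- NULL; hap_coords <- NULL
  if (!is.null(h)) {
    hc <- intersect(h$ids, s$id)
    haplotypes <- haplotype_set(h$ids, h$haplotype)
    if (length(hc)) {
      keep <- match(hc, h$ids)
      haplotypes <- haplotype_set(h$ids[keep], h$haplotype[keep])
      hap_coords <- s[match(hc, s$id), , drop = FALSE]
      class(hap_coords) <- c("spatial_frame", "data.frame")
    }
  }
  if (is.null(genotypes) && is.null(haplotypes))
    stop("no ids shared between any marker set and the coordinates")
  structure(list(genotypes = genotypes, coords = coords,
                 haplotypes = haplotypes, hap_coords = hap_coords,
                 dropped = dropped),
            class = "popgen_dataset")
}
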