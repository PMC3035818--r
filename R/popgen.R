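#' Expected heterozygosity from allele frequencies
#'
#' `He = 1 - sum(p^2)` (gene diversity).
#'
#' @param p vector of allele frequencies summing to 1
#' @return He in [0, 1]
#' @export
expected_heterozygosity <- function(p) {
  if (any(p < 0)) stop("input error: negative allele frequency")
  if (abs(sum(p) - 1) > 1e-8)
    stop("input error: frequencies must sum to 1 (got ", sum(p), ")")
  1 - sum(p^2)
}

#' Weir-Cockerham FST for two demes of allele copies
#'
#' The Weir & Cockerham (1984) variance-components estimator theta-hat in
#' its multi-allelic form, applied to allele copies (chromosomes), which
#' makes observed diploid data and simulated haploid chromosomes directly
#' comparable. Per allele, with r = 2 demes, n_i copies and frequencies
#' p_i:
#' \deqn{a = (nbar/nc) (s2 - (pbar(1-pbar) - s2 (r-1)/r) / (nbar-1))}
#' \deqn{b = (nbar/(nbar-1)) (pbar(1-pbar) - s2 (r-1)/r)}
#' and theta-hat = sum(a) / sum(a + b) over alleles. Negative values are
#' retained (no truncation): truncating would distort the lower tail of a
#' simulated null, which is exactly the region an introgression scan
#' interrogates.
#'
#' @param counts matrix of allele-copy counts, rows = alleles, exactly
#'   two columns (demes)
#' @return the FST estimate, or `NA` when the locus is monomorphic across
#'   both demes (the estimator is undefined there)
#' @export
fst_wc <- function(counts) {
  counts <- check_two_deme_counts(counts)
  if (nrow(counts) < 2L) return(NA_real_)
  n_i <- colSums(counts)
  if (any(n_i < 2L)) stop("sample-size error: need >= 2 copies per deme")
  r <- 2
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  p_i <- sweep(counts, 2L, n_i, "/")
  a_tot <- 0
  ab_tot <- 0
  for (al in seq_len(nrow(counts))) {
    p <- p_i[al, ]
    pbar <- sum(n_i * p) / sum(n_i)
    s2 <- sum(n_i * (p - pbar)^2) / ((r - 1) * nbar)
    inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
    a <- (nbar / nc) * (s2 - inner / (nbar - 1))
    b <- (nbar / (nbar - 1)) * inner
    a_tot <- a_tot + a
    ab_tot <- ab_tot + a + b
  }
  if (ab_tot == 0) return(NA_real_)
  a_tot / ab_tot
}

#' Hedrick's standardized G'ST for two demes
#'
#' `G_ST = (H_T - H_S)/H_T` with `H_S` the unweighted mean within-deme
#' expected heterozygosity and `H_T` the heterozygosity of the unweighted
#' mean allele frequencies; Hedrick's (2005) standardization divides by
#' the maximum attainable given `H_S`:
#' `G'_ST = G_ST (k - 1 + H_S) / ((k - 1)(1 - H_S))` with k = 2 demes.
#' Highly polymorphic markers (microsatellites) can then reach 1.
#'
#' @inheritParams fst_wc
#' @return G'ST, or `NA` when `H_T = 0` (monomorphic)
#' @export
gst_prime <- function(counts) {
  counts <- check_two_deme_counts(counts)
  n_i <- colSums(counts)
  if (any(n_i < 1L)) stop("sample-size error: empty deme")
  p_i <- sweep(counts, 2L, n_i, "/")
  Hs <- mean(apply(p_i, 2L, function(p) 1 - sum(p^2)))
  pbar <- rowMeans(p_i)
  Ht <- 1 - sum(pbar^2)
  if (Ht == 0) return(NA_real_)
  Gst <- (Ht - Hs) / Ht
  if (Hs >= 1) return(NA_real_)
  Gst * (1 + Hs) / (1 - Hs)
}

check_two_deme_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L)
    stop("usage error: counts must have exactly two columns (demes)")
  if (any(counts < 0)) stop("input error: negative allele count")
  counts[rowSums(counts) > 0, , drop = FALSE]
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g`
#' copies drawn without replacement from `N = sum(counts)` copies
#' (hypergeometric rarefaction):
#' `E[A_g] = sum_i (1 - choose(N - N_i, g)/choose(N, g))`.
#' Standardizes richness across unequal sample sizes.
#'
#' @param counts vector of allele-copy counts
#' @param g rarefaction sample size, `1 <= g <= sum(counts)`
#' @return expected allele count
#' @export
rarefied_allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N)
    stop("parameter error: g must lie in 1..", N)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Mean of a statistic over random inbred-line allele drops
#'
#' Residual heterozygosity in inbred lines is an artefact; averaging the
#' statistic over many random single-allele reductions
#' ([drop_inbred_alleles()]) removes it. Replicates on which the
#' statistic fails are skipped and counted; more than `max_skip_frac`
#' skipped is an error.
#'
#' @param gt a [genotype_table()]
#' @param statistic function taking a genotype_table and returning a
#'   numeric scalar or vector (constant length)
#' @param replicates number of random reductions (default 200)
#' @param max_skip_frac maximum tolerated fraction of failed replicates
#' @return mean of the statistic across replicates (element-wise, `NA`s
#'   removed per element), with attributes `replicates_used`, `skipped`
#' @export
inbred_drop_mean <- function(gt, statistic, replicates = 200,
                             max_skip_frac = 0.1) {
  stopifnot(inherits(gt, "genotype_table"), replicates >= 1)
  vals <- vector("list", replicates)
  skipped <- 0L
  for (r in seq_len(replicates)) {
    v <- tryCatch(statistic(drop_inbred_alleles(gt)),
                  error = function(e) NULL)
    if (is.null(v)) skipped <- skipped + 1L else vals[[r]] <- v
  }
  if (skipped > max_skip_frac * replicates)
    stop("statistic undefined on ", skipped, "/", replicates, " replicates")
  m <- colMeans(do.call(rbind, vals[!vapply(vals, is.null, TRUE)]),
                na.rm = TRUE)
  if (length(m) == 1L) m <- unname(m)
  attr(m, "replicates_used") <- replicates - skipped
  attr(m, "skipped") <- skipped
  m
}

#' Proportion-of-shared-alleles distance matrix between groups
#'
#' For pooled group allele frequencies, the distance between two groups
#' is `1 - (1/L) sum_loci sum_alleles min(p|g1, p|g2)`; loci at which
#' either group has no data are excluded pairwise (L is the per-pair
#' locus count).
#'
#' @param gt a [genotype_table()]
#' @param grouping vector of group labels, one per individual (`NA`
#'   excludes the individual)
#' @return symmetric distance matrix with zero diagonal
#' @export
dps_distance_matrix <- function(gt, grouping) {
  stopifnot(inherits(gt, "genotype_table"))
  grouping <- as.character(grouping)
  groups <- sort(unique(grouping[!is.na(grouping)]))
  if (length(groups) < 2L) stop("need at least 2 groups")
  L <- nrow(gt$loci)
  # per group x locus: named frequency vectors (NULL where no data)
  freqs <- lapply(groups, function(g) {
    rows <- which(grouping == g)
    lapply(seq_len(L), function(j) {
      cnt <- allele_counts(gt, j, rows)
      if (!length(cnt)) NULL else cnt / sum(cnt)
    })
  })
  has_data <- matrix(vapply(freqs, function(fg)
    vapply(fg, Negate(is.null), TRUE), logical(L)), nrow = L)
  if (any(colSums(has_data) == 0))
    stop("group error: group(s) without data at any locus: ",
         paste(groups[colSums(has_data) == 0], collapse = ", "))
  D <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (g1 in seq_along(groups)[-length(groups)]) {
    for (g2 in (g1 + 1L):length(groups)) {
      ok <- has_data[, g1] & has_data[, g2]
      if (!any(ok))
        stop("group error: no shared typed locus between ", groups[g1],
             " and ", groups[g2])
      shared <- vapply(which(ok), function(j) {
        p1 <- freqs[[g1]][[j]]; p2 <- freqs[[g2]][[j]]
        states <- union(names(p1), names(p2))
        q1 <- p1[states]; q1[is.na(q1)] <- 0
        q2 <- p2[states]; q2[is.na(q2)] <- 0
        sum(pmin(q1, q2))
      }, 0)
      D[g1, g2] <- D[g2, g1] <- 1 - mean(shared)
    }
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}).
#'
#' @param D symmetric distance matrix, zero diagonal, >= 3 taxa
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("size error: need >= 3 taxa, got ", nrow(D))
  if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  ape::nj(stats::as.dist(D))
}

#' Bootstrap support for the shared-alleles NJ tree
#'
#' Resamples loci with replacement, rebuilds the distance matrix and NJ
#' tree per replicate, and reports for each internal node of the
#' point-estimate tree the percentage of replicate trees containing the
#' same bipartition.
#'
#' @inheritParams dps_distance_matrix
#' @param replicates bootstrap replicates (default 100)
#' @return list with `tree` (the point-estimate `phylo`, node labels set
#'   to support percentages) and `support` (numeric vector per internal
#'   node)
#' @export
bootstrap_support <- function(gt, grouping, replicates = 100) {
  tree <- nj_tree(dps_distance_matrix(gt, grouping))
  L <- nrow(gt$loci)
  boot <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    boot[[b]] <- nj_tree(dps_distance_matrix(subset_loci(gt, idx), grouping))
  }
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / replicates
  tree$node.label <- support
  list(tree = tree, support = support)
}

#' Per-locus summary and differentiation statistics for a two-species
#' table
#'
#' For every locus: total distinct alleles, mean within-species expected
#' heterozygosity, Weir-Cockerham FST and Hedrick's G'ST on allele-copy
#' counts. Monomorphic loci get `NA` differentiation values (flagged
#' `undefined` downstream). Apply [inbred_drop_mean()] around this
#' function when the table holds inbred lines.
#'
#' @param gt a [genotype_table()]
#' @param species_a,species_b the two species labels (defaults: the two
#'   species present)
#' @return data.frame: locus, chromosome, allele_count, He, fst,
#'   gst_prime
#' @export
locus_stats <- function(gt, species_a = NULL, species_b = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  sp <- unique(gt$individuals$species)
  if (is.null(species_a) || is.null(species_b)) {
    if (length(sp) != 2L)
      stop("usage error: specify species_a/species_b (found ",
           length(sp), " species)")
    species_a <- sp[1L]; species_b <- sp[2L]
  }
  rows <- lapply(seq_len(nrow(gt$loci)), function(j) {
    m <- species_count_matrix(gt, j, species_a, species_b)
    p_i <- sweep(m, 2L, colSums(m), "/")
    data.frame(locus = gt$loci$name[j], chromosome = gt$loci$chromosome[j],
               allele_count = nrow(m),
               He = mean(apply(p_i, 2L, function(p) 1 - sum(p^2))),
               fst = fst_wc(m), gst_prime = gst_prime(m))
  })
  do.call(rbind, rows)
}
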