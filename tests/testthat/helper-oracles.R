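# Independent oracles and small fixture builders used across tests.
# Every oracle here is written from the definition of the quantity, by a
# route different from the package implementation.

# alignment from equal-length strings; species/collection default per id
toy_alignment <- function(seqs, species = NULL, site_mask = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (is.null(species)) species <- rep("sp1", length(seqs))
  alignment(seqs,
            data.frame(id = names(seqs), species = species,
                       collection = "c1", stringsAsFactors = FALSE),
            site_mask = site_mask)
}

# brute-force mean pairwise p-distance: explicit double loop over pairs
oracle_mean_pdist <- function(mat) {
  n <- nrow(mat)
  d <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d <- c(d, mean(mat[i, ] != mat[j, ]))
  mean(d)
}

# all compositions of n into exactly h positive parts (order ignored)
compositions <- function(n, h) {
  if (h == 1) return(list(n))
  out <- list()
  for (first in seq_len(n - h + 1)) {
    for (rest in compositions(n - first, h - 1)) {
      parts <- sort(c(first, rest), decreasing = TRUE)
      out[[paste(parts, collapse = ",")]] <- parts
    }
  }
  out
}

# Weir-Cockerham haploid FST via the mean-squares (ANOVA) formulation
oracle_fst_ms <- function(counts) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  n_i <- colSums(counts)
  r <- 2
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  p_i <- sweep(counts, 2, n_i, "/")
  num <- 0
  den <- 0
  for (al in seq_len(nrow(counts))) {
    p <- p_i[al, ]
    pw <- sum(n_i * p) / sum(n_i)
    MSP <- sum(n_i * (p - pw)^2) / (r - 1)
    MSG <- sum(n_i * p * (1 - p)) / sum(n_i - 1)
    num <- num + (MSP - MSG)
    den <- den + MSP + (nc - 1) * MSG
  }
  num / den
}

# rarefied richness by exhaustive enumeration of all g-subsets of copies
oracle_rarefaction <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# G'ST from pooled heterozygosities, computed step by step
oracle_gst_prime <- function(counts) {
  p1 <- counts[, 1] / sum(counts[, 1])
  p2 <- counts[, 2] / sum(counts[, 2])
  Hs <- ((1 - sum(p1^2)) + (1 - sum(p2^2))) / 2
  pbar <- (p1 + p2) / 2
  Ht <- 1 - sum(pbar^2)
  Gst <- (Ht - Hs) / Ht
  Gst * (2 - 1 + Hs) / ((2 - 1) * (1 - Hs))
}

# proportion-of-shared-alleles distance for two explicit frequency lists
oracle_dps <- function(freq1, freq2) {
  stopifnot(length(freq1) == length(freq2))
  shared <- numeric(length(freq1))
  for (l in seq_along(freq1)) {
    states <- union(names(freq1[[l]]), names(freq2[[l]]))
    s <- 0
    for (a in states) {
      q1 <- if (a %in% names(freq1[[l]])) freq1[[l]][[a]] else 0
      q2 <- if (a %in% names(freq2[[l]])) freq2[[l]][[a]] else 0
      s <- s + min(q1, q2)
    }
    shared[l] <- s
  }
  1 - mean(shared)
}

# small two-species genotype table from explicit allele matrices
toy_genotypes <- function(a1, a2, species, inbred = NULL,
                          chromosome = NULL) {
  n <- nrow(a1)
  L <- ncol(a1)
  if (is.null(inbred)) inbred <- rep(FALSE, n)
  if (is.null(chromosome)) chromosome <- rep("3", L)
  genotype_table(
    data.frame(id = sprintf("i%02d", seq_len(n)), species = species,
               collection = "c1", inbred = inbred,
               stringsAsFactors = FALSE),
    data.frame(name = sprintf("L%02d", seq_len(L)), chromosome = chromosome,
               stringsAsFactors = FALSE),
    a1, a2)
}

# segregating-site counts from msprime (independent coalescent oracle);
# scaling: haploid lineages in demes of size 2*N0 give the per-pair
# coalescence rate 1/(2*N0) per generation, i.e. rate 2 per 4*N0 unit
msprime_segsites <- function(n1, n2, theta, tau, replicates, seed) {
  script <- sprintf('
import msprime
N0 = 500
dem = msprime.Demography()
dem.add_population(name="A", initial_size=2*N0)
dem.add_population(name="B", initial_size=2*N0)
dem.add_population(name="anc", initial_size=2*N0)
dem.add_population_split(time=%f*4*N0, derived=["A","B"], ancestral="anc")
reps = msprime.sim_ancestry(samples={"A":%d,"B":%d}, ploidy=1,
    demography=dem, sequence_length=1, num_replicates=%d, random_seed=%d)
for i, ts in enumerate(reps):
    mts = msprime.sim_mutations(ts, rate=%f/(4*N0),
        discrete_genome=False, random_seed=%d+i)
    print(mts.num_sites)
', tau, n1, n2, replicates, seed, theta, seed + 1)
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE))
  as.integer(out)
}
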