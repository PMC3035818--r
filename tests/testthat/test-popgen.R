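test_that("expected heterozygosity follows 1 - sum(p^2)", {
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(rep(0.25, 4)), 0.75)
  expect_error(expected_heterozygosity(c(-0.1, 1.1)), "input")
  expect_error(expected_heterozygosity(c(0.3, 0.3)), "input")
})

test_that("Weir-Cockerham FST matches the independent mean-squares oracle", {
  # complete fixation
  expect_equal(fst_wc(cbind(c(10, 0), c(0, 10))), 1)
  # worked small instance: 4+4 copies, counts A:3/1, B:1/3
  m <- cbind(c(3, 1), c(1, 3))
  expect_equal(fst_wc(m), oracle_fst_ms(m), tolerance = 1e-12)
  # no differentiation with large equal samples
  expect_lt(abs(fst_wc(cbind(c(120, 80), c(120, 80)))), 0.02)
  # monomorphic across both demes is undefined
  expect_true(is.na(fst_wc(cbind(5, 7))))
  # random toy instances (<= 10 copies per deme), exact match to oracle
  set.seed(55)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    m <- cbind(rmultinom(1, sample(4:10, 1), runif(k))[, 1],
               rmultinom(1, sample(4:10, 1), runif(k))[, 1])
    if (any(colSums(m) < 2) || sum(rowSums(m) > 0) < 2) next
    expect_equal(fst_wc(m), oracle_fst_ms(m), tolerance = 1e-12)
    # invariance under allele relabelling (row permutation)
    expect_equal(fst_wc(m[sample(nrow(m)), , drop = FALSE]), fst_wc(m),
                 tolerance = 1e-12)
  }
  expect_error(fst_wc(cbind(c(1, 0), c(3, 3))), "sample-size")
  expect_error(fst_wc(cbind(1, 2, 3)), "two columns")
})

test_that("G'ST standardization behaves as Hedrick's correction", {
  # demes fixed for different alleles: Hs = 0, G = G' = 1
  expect_equal(gst_prime(cbind(c(8, 0), c(0, 8))), 1)
  # equal frequencies: no differentiation
  expect_equal(gst_prime(cbind(c(6, 2), c(6, 2))), 0)
  expect_true(is.na(gst_prime(cbind(4, 4))))
  set.seed(56)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    m <- cbind(rmultinom(1, sample(5:12, 1), runif(k))[, 1],
               rmultinom(1, sample(5:12, 1), runif(k))[, 1])
    if (sum(rowSums(m) > 0) < 2) next
    gp <- gst_prime(m)
    expect_equal(gp, oracle_gst_prime(m[rowSums(m) > 0, , drop = FALSE]),
                 tolerance = 1e-12)
    # the multiplier is >= 1, and G' never exceeds 1
    p1 <- m[, 1] / sum(m[, 1]); p2 <- m[, 2] / sum(m[, 2])
    Hs <- mean(c(1 - sum(p1^2), 1 - sum(p2^2)))
    Ht <- 1 - sum(((p1 + p2) / 2)^2)
    G <- (Ht - Hs) / Ht
    if (G >= 0) expect_gte(gp, G - 1e-12)
    expect_lte(gp, 1 + 1e-12)
  }
})

test_that("rarefied richness equals exhaustive subsample enumeration", {
  expect_equal(rarefied_allelic_richness(c(5, 3, 2), 10), 3)
  expect_equal(rarefied_allelic_richness(c(5, 3, 2), 1), 1)
  expect_equal(rarefied_allelic_richness(c(5, 3, 2), 5),
               oracle_rarefaction(c(5, 3, 2), 5), tolerance = 1e-12)
  expect_equal(rarefied_allelic_richness(c(4, 4, 1, 1), 6),
               oracle_rarefaction(c(4, 4, 1, 1), 6), tolerance = 1e-12)
  # nondecreasing in g
  counts <- c(6, 3, 1)
  vals <- vapply(1:10, rarefied_allelic_richness, 0, counts = counts)
  expect_true(all(diff(vals) >= -1e-12))
  expect_error(rarefied_allelic_richness(c(5, 3, 2), 11), "parameter")
})

test_that("inbred allele drop averages to the exact two-outcome expectation", {
  # 5 homozygote AA individuals + 1 inbred heterozygote A/B, one locus;
  # dropping keeps A or B with probability 1/2 each
  a1 <- matrix(c(rep(1L, 5), 1L), ncol = 1)
  a2 <- matrix(c(rep(1L, 5), 2L), ncol = 1)
  gt <- toy_genotypes(a1, a2, species = rep("m", 6),
                      inbred = c(rep(FALSE, 5), TRUE))
  he_stat <- function(g) {
    cnt <- allele_counts(g, 1)
    expected_heterozygosity(cnt / sum(cnt))
  }
  # outcome A kept: 11 A copies -> He = 0; B kept: 10 A + 1 B
  he_b <- expected_heterozygosity(c(10, 1) / 11)
  analytic <- (0 + he_b) / 2
  set.seed(60)
  reps <- 400
  vals <- replicate(reps, he_stat(drop_inbred_alleles(gt)))
  m <- inbred_drop_mean(gt, he_stat, replicates = reps)
  expect_lt(abs(m - analytic), 3 * sd(vals) / sqrt(reps))

  # all-homozygote tables are unchanged by the drop for any replicates
  gt_hom <- toy_genotypes(a1, a1, species = rep("m", 6),
                          inbred = rep(TRUE, 6))
  expect_equal(as.numeric(inbred_drop_mean(gt_hom, he_stat, replicates = 3)),
               he_stat(gt_hom))
  # fixed seed reproduces the value
  set.seed(61)
  v1 <- inbred_drop_mean(gt, he_stat, replicates = 1)
  set.seed(61)
  expect_identical(inbred_drop_mean(gt, he_stat, replicates = 1), v1)
  expect_error(inbred_drop_mean(gt, function(g) stop("boom"),
                                replicates = 10), "undefined")
})

test_that("shared-alleles distance matches direct evaluation", {
  # one locus: g1 = {A:.5, B:.5}, g2 = {A:1}
  a1 <- matrix(c(1L, 1L, 1L, 1L), ncol = 1)
  a2 <- matrix(c(2L, 2L, 1L, 1L), ncol = 1)
  gt <- toy_genotypes(a1, a2, species = rep("m", 4))
  D <- dps_distance_matrix(gt, c("g1", "g1", "g2", "g2"))
  expect_equal(D["g1", "g2"], 0.5)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))

  # identical profiles -> 0; disjoint allele sets -> 1
  gt2 <- toy_genotypes(matrix(c(1L, 1L, 3L, 3L), ncol = 1),
                       matrix(c(2L, 2L, 4L, 4L), ncol = 1),
                       species = rep("m", 4))
  D2 <- dps_distance_matrix(gt2, c("g1", "g1", "g2", "g2"))
  expect_equal(D2["g1", "g2"], 1)
  D3 <- dps_distance_matrix(gt2, c("g1", "g2", "g1", "g2"))
  expect_equal(D3["g1", "g2"], 0)

  # multi-locus case against the step-by-step oracle
  set.seed(62)
  a1 <- matrix(sample(1:3, 12, TRUE), ncol = 2)
  a2 <- matrix(sample(1:3, 12, TRUE), ncol = 2)
  gt3 <- toy_genotypes(a1, a2, species = rep("m", 6))
  grp <- c("x", "x", "x", "y", "y", "y")
  D4 <- dps_distance_matrix(gt3, grp)
  f <- function(rows, j) {
    cnt <- allele_counts(gt3, j, rows)
    cnt / sum(cnt)
  }
  fx <- lapply(1:2, function(j) f(1:3, j))
  fy <- lapply(1:2, function(j) f(4:6, j))
  expect_equal(D4["x", "y"], oracle_dps(fx, fy), tolerance = 1e-12)
})

test_that("NJ recovers additive trees and bootstrap saturates on constant data", {
  # additive distances from the unrooted tree ((A,B),(C,D)) with known
  # branch lengths: A=1, B=2, C=3, D=4, internal = 5
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 1 + 2
  D["A", "C"] <- D["C", "A"] <- 1 + 5 + 3
  D["A", "D"] <- D["D", "A"] <- 1 + 5 + 4
  D["B", "C"] <- D["C", "B"] <- 2 + 5 + 3
  D["B", "D"] <- D["D", "B"] <- 2 + 5 + 4
  D["C", "D"] <- D["D", "C"] <- 3 + 4
  tr <- nj_tree(D)
  # the AB|CD bipartition must be present: A,B form a clade when rooted at C
  rooted <- ape::root(tr, "C", resolve.root = TRUE)
  tips_ab <- ape::extract.clade(
    rooted, ape::getMRCA(rooted, c("A", "B")))$tip.label
  expect_setequal(tips_ab, c("A", "B"))
  # and NJ reproduces the generating branch lengths on additive input
  expect_equal(sum(tr$edge.length), 1 + 2 + 3 + 4 + 5, tolerance = 1e-12)

  # 3 taxa: unique topology, lengths solve the three-point formulas
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(D3)
  len <- stats::setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])],
                         tr3$tip.label)
  expect_equal(len[["x"]], (3 + 5 - 6) / 2)
  expect_equal(len[["y"]], (3 + 6 - 5) / 2)
  expect_equal(len[["z"]], (5 + 6 - 3) / 2)
  expect_error(nj_tree(D3[1:2, 1:2]), "size")

  # bootstrap over identical loci: every recovered bipartition at 100%
  set.seed(63)
  base1 <- matrix(rep(c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L), 5), ncol = 5)
  gt <- toy_genotypes(base1, base1, species = rep("m", 8))
  grp <- rep(c("a", "b", "c", "d"), each = 2)
  bs <- bootstrap_support(gt, grp, replicates = 25)
  expect_true(all(bs$support == 100))
})

test_that("per-locus stats flag monomorphic loci as undefined", {
  set.seed(64)
  a1 <- cbind(sample(1:3, 8, TRUE), 5L)
  a2 <- cbind(sample(1:3, 8, TRUE), 5L)
  gt <- toy_genotypes(a1, a2, species = rep(c("mau", "sim"), each = 4))
  st <- locus_stats(gt)
  expect_equal(nrow(st), 2L)
  expect_true(is.na(st$fst[2]))
  expect_true(is.na(st$gst_prime[2]))
  expect_equal(st$allele_count[2], 1L)
  expect_equal(st$He[2], 0)
})
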