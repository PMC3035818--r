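test_that("FASTA reading records gap columns and enforces metadata", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT", ">c", "ACGA", ">d", "ACGT"), fa)
  meta <- data.frame(id = c("a", "b", "c", "d"), species = "sp1",
                     collection = "c1")
  aln <- read_alignment(fa, meta)
  expect_equal(length(aln$analysed), 4L)

  writeLines(c(">a", "AC-T", ">b", "ACGT", ">c", "ACGA", ">d", "ACGT"), fa)
  aln <- read_alignment(fa, meta)
  expect_equal(length(aln$analysed), 3L)
  expect_equal(aln$excluded, 3L)

  expect_error(read_alignment(fa, meta[1:3, ]), "metadata")
  writeLines(c(">a", "ACGT", ">b", "ACG"), fa)
  expect_error(read_alignment(fa, meta), "unequal")
})

test_that("diversity summary reproduces worked haplotype-diversity and JC values", {
  # monomorphic
  d <- diversity_summary(toy_alignment(rep("ACGTACGT", 4)))
  expect_equal(d$S, 0L)
  expect_equal(d$h, 1L)
  expect_equal(d$Hd, 0)
  expect_equal(d$pi_jc, 0)

  # two haplotypes at counts 2 and 2: Hd = (4/3)(1 - 0.5)
  d <- diversity_summary(toy_alignment(c("AAAA", "AAAA", "AAAT", "AAAT")))
  expect_equal(d$h, 2L)
  expect_equal(d$Hd, 2 / 3, tolerance = 1e-12)
  expect_equal(round(d$Hd, 2), 0.67)

  # two sequences, 100 sites, 1 difference
  s <- strrep("A", 100)
  s2 <- paste0(strrep("A", 99), "T")
  d <- diversity_summary(toy_alignment(c(s, s2)))
  expect_equal(d$pi_raw, 0.01)
  expect_equal(d$pi_jc, -0.75 * log(1 - 0.04 / 3), tolerance = 1e-12)
  expect_equal(d$pi_jc, 0.010067, tolerance = 1e-4)

  expect_error(diversity_summary(toy_alignment("ACGT")), "sample-size")
})

test_that("JC correction is only defined below saturation", {
  a <- toy_alignment(c("AAAA", "TTTT"))  # p-distance 1
  expect_error(diversity_summary(a), "Jukes-Cantor")
})

test_that("Hd is label-invariant and maximal at uniform haplotype counts", {
  hd <- function(counts) {
    n <- sum(counts)
    p <- counts / n
    n * (1 - sum(p^2)) / (n - 1)
  }
  for (n in 4:8) {
    for (h in 2:min(n, 4)) {
      comps <- compositions(n, h)
      vals <- vapply(comps, hd, 0)
      uniform_like <- vapply(comps, function(cc) max(cc) - min(cc) <= 1, TRUE)
      expect_true(all(vals[uniform_like] >= max(vals) - 1e-12),
                  label = sprintf("n=%d h=%d", n, h))
    }
  }
  # relabelling: permuting which haplotype gets which count changes nothing
  a1 <- toy_alignment(c("AA", "AA", "AT", "GG"))
  a2 <- toy_alignment(c("GG", "AT", "AA", "AA"))
  expect_equal(diversity_summary(a1)$Hd, diversity_summary(a2)$Hd)
})

test_that("pi_raw equals the brute-force pairwise average and is duplication-invariant", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    # sequences near a common backbone keep p-distances in the JC domain
    backbone <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    mat <- t(vapply(seq_len(n), function(i) {
      s <- backbone
      pos <- sample(12, 3)
      s[pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
      s
    }, character(12)))
    rownames(mat) <- paste0("s", 1:n)
    aln <- alignment(mat, data.frame(id = rownames(mat), species = "x",
                                     collection = "c"))
    d <- diversity_summary(aln)
    expect_equal(d$pi_raw, oracle_mean_pdist(mat), tolerance = 1e-12)
    # duplicating every sequence leaves the frequency-weighted diversity
    # pi_raw * (n-1)/n (= sum_i sum_j p_i p_j d_ij) unchanged
    mat2 <- rbind(mat, mat)
    rownames(mat2) <- paste0("s", 1:(2 * n))
    aln2 <- alignment(mat2, data.frame(id = rownames(mat2), species = "x",
                                       collection = "c"))
    d2 <- diversity_summary(aln2)
    expect_equal(d2$pi_raw * (2 * n - 1) / (2 * n),
                 d$pi_raw * (n - 1) / n, tolerance = 1e-12)
  }
})

test_that("between-species summary counts fixed and shared polymorphisms", {
  a <- toy_alignment(c("AAAA", "AAAA", "AAAT", "AAAT"),
                     species = c("A", "A", "B", "B"))
  bs <- between_species_summary(a, "A", "B")
  expect_equal(bs$F, 1L)
  expect_equal(bs$S_star, 0L)

  a <- toy_alignment(c("AC", "AT", "AC", "AT"),
                     species = c("A", "A", "B", "B"))
  bs <- between_species_summary(a, "A", "B")
  expect_equal(bs$F, 0L)
  expect_equal(bs$S_star, 1L)

  a <- toy_alignment(c("AAAA", "AAGG"), species = c("A", "B"))
  expect_equal(between_species_summary(a, "A", "B")$Ks,
               -0.75 * log(1 - 2 / 3), tolerance = 1e-12)

  expect_error(between_species_summary(a, "A", "Z"), "sample-size")
})

test_that("F + S_star never exceeds the segregating-site count", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 6
    mat <- matrix(sample(c("A", "C"), n * 10, replace = TRUE), nrow = n)
    rownames(mat) <- paste0("s", 1:n)
    aln <- alignment(mat, data.frame(id = rownames(mat),
                                     species = rep(c("A", "B"), each = 3),
                                     collection = "c"))
    bs <- between_species_summary(aln, "A", "B")
    S_total <- diversity_summary(aln)$S
    expect_lte(bs$F + bs$S_star, S_total)
  }
})

test_that("silent-site mask keeps degenerate third positions only", {
  # codon 1 = GGx (glycine, 4-fold), codon 2 = ATG / ATA (3rd pos of ATG
  # family: only ATG is Met -> nondegenerate for ATG)
  a <- toy_alignment(c("GGAATG", "GGCATG"))
  mask <- silent_site_mask(a)
  expect_true(3 %in% mask)    # glycine third position
  expect_false(6 %in% mask)   # ATG third position, Met is 1-fold
  expect_false(any(c(1, 2, 4, 5) %in% mask))

  expect_error(silent_site_mask(toy_alignment(c("AC", "AC"))), "frame")
  # internal stop codon fixed in every sequence
  expect_error(silent_site_mask(toy_alignment(c("TAAGGG", "TAAGGG"))),
               "stop")
})

test_that("diversity_table groups sequences and keeps Table-like order", {
  a <- toy_alignment(c("AAAA", "AAAT", "AACC", "AACC"))
  tab <- diversity_table(a, stats::setNames(c("g1", "g1", "g2", "g2"),
                                            paste0("s", 1:4)))
  expect_equal(names(tab), c("group", "n", "S", "h", "Hd", "pi_jc", "pi_raw"))
  expect_equal(tab$h, c(2L, 1L))
  # singleton groups are skipped, not an error
  tab <- diversity_table(a, stats::setNames(c("g1", "g1", "g1", "g2"),
                                            paste0("s", 1:4)))
  expect_equal(tab$group, "g1")
})
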