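#' Specification for a study-shaped synthetic data set
#'
#' Defaults emulate the structure of the motivating study system: 125
#' recipient-species (`mauritiana`) individuals and 15 donor-species
#' (`simulans`) individuals typed at 25 microsatellites spread over the
#' X, 2nd, 3rd and 4th chromosomes (the single 4th-chromosome locus is
#' forced monomorphic across both species), a fraction of inbred
#' isofemale lines, a two-population split at `tau` = 1.25 (4*N0 units,
#' the reference simulation setting), per-locus theta = 4, and an mtDNA
#' haplogroup plan in which an introgressed recipient haplotype sits
#' exactly 3 silent substitutions from its nearest donor haplotype over
#' a 737-site silent mask.
#'
#' The haplogroup plan is a data.frame with one row per haplotype class:
#' `class` (haplotype name), `haplogroup`, `species`, `count` (sequences
#' carrying it), `donor` (class it derives from; `NA` = the backbone
#' sequence) and `k` (silent substitutions separating it from its
#' donor). Classes are planted on a star-like scaffold with disjoint
#' substitution sites, so distances along donor chains are additive.
#'
#' @param n_mau,n_sim individuals per species
#' @param n_loci number of microsatellite loci
#' @param split_tau species split time in 4*N0 units
#' @param theta per-locus scaled mutation rate
#' @param inbred_fraction fraction of recipient individuals flagged as
#'   inbred lines
#' @param n_introgressed_loci loci whose recipient lineages are drawn
#'   from the donor deme (split effectively at tau = 0)
#' @param haplogroup_plan see Details; `NULL` for the default plan
#' @param silent_sites size of the silent-site mask
#' @param aln_length total alignment length (>= `silent_sites`)
#' @param mu silent substitution rate per site per year per lineage
#' @return object of class `"synth_spec"`
#' @export
synth_spec <- function(n_mau = 125, n_sim = 15, n_loci = 25,
                       split_tau = 1.25, theta = 4,
                       inbred_fraction = 0.3, n_introgressed_loci = 5,
                       haplogroup_plan = NULL,
                       silent_sites = 737, aln_length = 2088,
                       mu = 1.6e-8) {
  if (is.null(haplogroup_plan))
    haplogroup_plan <- default_haplogroup_plan(n_mau, n_sim)
  plan <- as.data.frame(haplogroup_plan, stringsAsFactors = FALSE)
  need <- c("class", "haplogroup", "species", "count", "donor", "k")
  if (!all(need %in% names(plan)))
    stop("haplogroup_plan needs columns ", paste(need, collapse = ", "))
  if (any(plan$count < 0) || n_loci < 1 || n_mau < 1 || n_sim < 1 ||
      inbred_fraction < 0 || inbred_fraction > 1 ||
      n_introgressed_loci < 0 || n_introgressed_loci > n_loci)
    stop("parameter error: invalid synthetic-data specification")
  if (sum(plan$k) > silent_sites)
    stop("parameter error: substitution budget ", sum(plan$k),
         " exceeds silent_sites = ", silent_sites)
  bad_donor <- setdiff(plan$donor[!is.na(plan$donor)], plan$class)
  if (length(bad_donor))
    stop("unknown donor class(es): ", paste(bad_donor, collapse = ", "))
  if (aln_length < silent_sites)
    stop("parameter error: aln_length < silent_sites")
  structure(list(n_mau = n_mau, n_sim = n_sim, n_loci = n_loci,
                 split_tau = split_tau, theta = theta,
                 inbred_fraction = inbred_fraction,
                 n_introgressed_loci = n_introgressed_loci,
                 haplogroup_plan = plan, silent_sites = silent_sites,
                 aln_length = aln_length, mu = mu),
            class = "synth_spec")
}

# Default mtDNA haplotype-class plan: a shared maI/siIII haplogroup, a
# divergent endemic maII, donor-species siI and two siII haplotypes, and
# an introgressed maIII pair — MAU3 identical to the siII_MD haplotype,
# MAU4 three silent substitutions from siII_KY (which itself sits two
# from siII_MD, so MAU3 and MAU4 are five apart).
default_haplogroup_plan <- function(n_mau = 125, n_sim = 15) {
  n_maII <- max(1L, round(0.15 * n_mau))
  n_maIII <- 4L
  n_maI <- n_mau - n_maII - n_maIII
  n_siIII <- max(1L, round(0.2 * n_sim))
  n_siI <- 1L
  n_siII_KY <- max(1L, floor((n_sim - n_siIII - n_siI) / 2))
  n_siII_MD <- n_sim - n_siIII - n_siI - n_siII_KY
  data.frame(
    class = c("siIII", "maI", "maII", "siI", "siII_MD", "siII_KY",
              "maIII_MAU3", "maIII_MAU4"),
    haplogroup = c("siIII", "maI", "maII", "siI", "siII", "siII",
                   "maIII", "maIII"),
    species = c("simulans", "mauritiana", "mauritiana", "simulans",
                "simulans", "simulans", "mauritiana", "mauritiana"),
    count = c(n_siIII, n_maI, n_maII, n_siI, n_siII_MD, n_siII_KY,
              2L, 2L),
    donor = c(NA, "siIII", NA, NA, NA, "siII_MD", "siII_MD", "siII_KY"),
    k = c(12L, 0L, 60L, 40L, 20L, 2L, 0L, 3L),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic mtDNA alignment with silent-site mask
#'
#' Builds a random backbone sequence, then plants each haplotype class of
#' the plan by substituting exactly `k` fresh silent-mask sites of its
#' donor class's sequence (donor `NA` = the backbone). Substituted site
#' sets are disjoint across classes (infinite-sites-like), so pairwise
#' masked distances along donor chains are additive and the planted
#' substitution counts are exact. Uses R's global RNG.
#'
#' @param spec a [synth_spec()]
#' @return an [alignment()] whose `meta` carries an extra `haplogroup`
#'   column; sequence ids are `<class>_<i>`
#' @export
gen_alignment <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  plan <- spec$haplogroup_plan
  backbone <- sample(c("A", "C", "G", "T"), spec$aln_length, replace = TRUE)
  mask <- sort(sample.int(spec$aln_length, spec$silent_sites))
  avail <- sample(mask)              # shuffled, consumed without reuse
  class_seq <- list()
  used <- 0L
  resolve <- function(cl) {
    if (!is.null(class_seq[[cl]])) return(class_seq[[cl]])
    row <- plan[plan$class == cl, ]
    base <- if (is.na(row$donor)) backbone else resolve(row$donor)
    s <- base
    if (row$k > 0L) {
      sites <- avail[used + seq_len(row$k)]
      used <<- used + row$k
      for (pos in sites)
        s[pos] <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1L)
    }
    class_seq[[cl]] <<- s
    s
  }
  # resolve in donor order (donors first)
  remaining <- plan$class
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(cl) {
      d <- plan$donor[plan$class == cl]
      is.na(d) || !is.null(class_seq[[d]])
    }, TRUE)]
    for (cl in ready) resolve(cl)
    remaining <- setdiff(remaining, ready)
  }
  seqs <- list(); meta <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    if (row$count == 0L) next
    ids <- sprintf("%s_%d", row$class, seq_len(row$count))
    for (id in ids) seqs[[id]] <- class_seq[[row$class]]
    meta[[i]] <- data.frame(id = ids, species = row$species,
                            collection = "SYN",
                            haplogroup = row$haplogroup,
                            stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, seqs)
  alignment(mat, do.call(rbind, meta), site_mask = mask)
}

#' Generate a synthetic microsatellite genotype table
#'
#' Neutral loci are simulated under the isolation model at `split_tau`
#' with `2 * n_mau + 2 * n_sim` chromosomes, converted to allele states
#' by the stepwise mutation model, and paired into diploids. Introgressed
#' loci are simulated identically but at `tau = 0`, i.e. the recipient
#' sample's lineages are drawn from the same pool as the donor's, which
#' yields genuinely reduced differentiation rather than copied alleles.
#' One 4th-chromosome locus is forced monomorphic across both species.
#' The first `round(inbred_fraction * n_mau)` recipient individuals are
#' flagged inbred. Uses R's global RNG.
#'
#' @param spec a [synth_spec()]
#' @param baseline display offset added to allele states (repeat units)
#' @return a [genotype_table()]; attribute `introgressed_loci` names the
#'   loci simulated at tau = 0
#' @export
gen_genotype_table <- function(spec, baseline = 100L) {
  stopifnot(inherits(spec, "synth_spec"))
  n_mau <- spec$n_mau; n_sim <- spec$n_sim; n_loci <- spec$n_loci
  chrom <- locus_chromosomes(n_loci)
  mono_locus <- which(chrom == "4")[1L]
  candidates <- setdiff(seq_len(n_loci), mono_locus)
  intro_loci <- if (spec$n_introgressed_loci > 0L)
    sort(sample(candidates, spec$n_introgressed_loci)) else integer(0)
  n1 <- 2L * n_mau; n2 <- 2L * n_sim
  a1 <- matrix(NA_integer_, n_mau + n_sim, n_loci)
  a2 <- matrix(NA_integer_, n_mau + n_sim, n_loci)
  for (j in seq_len(n_loci)) {
    if (!is.na(mono_locus) && j == mono_locus) {
      a1[, j] <- a2[, j] <- baseline
      next
    }
    tau_j <- if (j %in% intro_loci) 0 else spec$split_tau
    samp <- simulate_msat_locus(
      isolation_model(n1, n2, spec$theta, tau_j), baseline)
    # consecutive chromosomes pair into diploids; deme 1 first
    a1[, j] <- samp$alleles[seq(1L, n1 + n2, by = 2L)]
    a2[, j] <- samp$alleles[seq(2L, n1 + n2, by = 2L)]
  }
  individuals <- data.frame(
    id = c(sprintf("MAU%03d", seq_len(n_mau)),
           sprintf("SIM%03d", seq_len(n_sim))),
    species = rep(c("mauritiana", "simulans"), c(n_mau, n_sim)),
    collection = "SYN",
    inbred = c(seq_len(n_mau) <= round(spec$inbred_fraction * n_mau),
               rep(FALSE, n_sim)),
    stringsAsFactors = FALSE)
  loci <- data.frame(name = sprintf("msat%02d", seq_len(n_loci)),
                     chromosome = chrom, stringsAsFactors = FALSE)
  gt <- genotype_table(individuals, loci, a1, a2)
  attr(gt, "introgressed_loci") <- loci$name[intro_loci]
  gt
}

# X / 2nd / 3rd / 4th chromosome labels for n loci: one 4th-chromosome
# locus, the rest split roughly 1:2:2 across X, 2nd and 3rd
locus_chromosomes <- function(n_loci) {
  if (n_loci == 25L) return(rep(c("X", "2", "3", "4"), c(6L, 9L, 9L, 1L)))
  n4 <- if (n_loci >= 4L) 1L else 0L
  rest <- n_loci - n4
  nx <- max(1L, round(rest / 5))
  n2 <- floor((rest - nx) / 2)
  rep(c("X", "2", "3", "4"), c(nx, n2, rest - nx - n2, n4))
}

#' Write a complete synthetic data set to disk
#'
#' FASTA alignment + sequence metadata CSV (with haplogroup column) +
#' genotype CSV + loci CSV, in the dialects the package readers consume.
#'
#' @param spec a [synth_spec()]
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths (`fasta`, `meta`,
#'   `genotypes`, `loci`, `mask`)
#' @export
write_synthetic_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aln <- gen_alignment(spec)
  gt <- gen_genotype_table(spec)
  paths <- c(fasta = file.path(dir, "mtdna_alignment.fasta"),
             meta = file.path(dir, "sequence_metadata.csv"),
             genotypes = file.path(dir, "genotypes.csv"),
             loci = file.path(dir, "loci.csv"),
             mask = file.path(dir, "silent_sites.txt"))
  write_alignment(aln, paths["fasta"])
  utils::write.csv(aln$meta, paths["meta"], row.names = FALSE, quote = FALSE)
  write_genotype_table(gt, paths["genotypes"], paths["loci"])
  writeLines(as.character(aln$site_mask), paths["mask"])
  attr(paths, "introgressed_loci") <- attr(gt, "introgressed_loci")
  paths
}
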