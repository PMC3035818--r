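#' Diploid microsatellite genotype table
#'
#' Individuals x loci table of allele sizes (repeat units or display
#' sizes), with per-individual species/collection/inbred metadata and
#' per-locus chromosome labels. Missing genotypes are `NA` in both allele
#' slots; a genotype with one `NA` slot is a deliberate single allele
#' copy (e.g. after the inbred-line allele drop, or a hemizygous male at
#' an X-linked locus).
#'
#' @param individuals data.frame with columns `id`, `species`,
#'   `collection`, `inbred` (logical)
#' @param loci data.frame with columns `name`, `chromosome` (labels from
#'   `X`, `2`, `3`, `4`)
#' @param a1,a2 integer matrices (individuals x loci) of allele states
#' @return object of class `"genotype_table"`
#' @export
genotype_table <- function(individuals, loci, a1, a2) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "species", "collection", "inbred") %in%
                  names(individuals)),
            all(c("name", "chromosome") %in% names(loci)))
  if (!all(loci$chromosome %in% c("X", "2", "3", "4")))
    stop("chromosome labels must be among X, 2, 3, 4")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == c(nrow(individuals), nrow(loci))) ||
      !all(dim(a2) == dim(a1)))
    stop("shape error: allele matrices must be individuals x loci")
  dimnames(a1) <- dimnames(a2) <- list(individuals$id, loci$name)
  structure(list(individuals = individuals, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype table:", nrow(x$individuals), "individuals x",
      nrow(x$loci), "loci;",
      sum(x$individuals$inbred), "inbred-flagged;",
      "species:", paste(unique(x$individuals$species), collapse = ", "), "\n")
  invisible(x)
}

#' Read a genotype table from CSV
#'
#' Expected dialect: columns `id`, `species`, `collection`, `inbred`,
#' then one pair of columns per locus named `<locus>_1`, `<locus>_2`;
#' missing alleles are empty fields. Chromosome labels come from a
#' companion loci CSV with columns `name`, `chromosome`; if omitted all
#' loci are labelled `3`.
#'
#' @param path genotype CSV path
#' @param loci_path optional loci metadata CSV path
#' @return a [genotype_table()]
#' @export
read_genotype_table <- function(path, loci_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("id", "species", "collection", "inbred")
  if (!all(meta_cols %in% names(df)))
    stop("genotype CSV must start with columns ",
         paste(meta_cols, collapse = ", "))
  allele_cols <- setdiff(names(df), meta_cols)
  lnames <- unique(sub("_[12]$", "", allele_cols))
  if (!setequal(allele_cols, c(paste0(lnames, "_1"), paste0(lnames, "_2"))))
    stop("allele columns must come in <locus>_1/<locus>_2 pairs")
  a1 <- as.matrix(df[paste0(lnames, "_1")])
  a2 <- as.matrix(df[paste0(lnames, "_2")])
  mode(a1) <- mode(a2) <- "integer"
  loci <- if (is.null(loci_path))
    data.frame(name = lnames, chromosome = "3", stringsAsFactors = FALSE)
  else {
    l <- utils::read.csv(loci_path, stringsAsFactors = FALSE,
                         colClasses = "character")
    l[match(lnames, l$name), c("name", "chromosome")]
  }
  genotype_table(df[meta_cols], loci, a1, a2)
}

#' Write a genotype table (and its loci metadata) to CSV
#'
#' @param gt a [genotype_table()]
#' @param path genotype CSV path
#' @param loci_path optional loci metadata CSV path
#' @return `path`, invisibly
#' @export
write_genotype_table <- function(gt, path, loci_path = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  out <- gt$individuals[c("id", "species", "collection", "inbred")]
  for (j in seq_len(nrow(gt$loci))) {
    out[[paste0(gt$loci$name[j], "_1")]] <- gt$a1[, j]
    out[[paste0(gt$loci$name[j], "_2")]] <- gt$a2[, j]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(loci_path))
    utils::write.csv(gt$loci, loci_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep a subset of loci
#' @param gt a [genotype_table()]
#' @param idx locus indices or names
#' @export
subset_loci <- function(gt, idx) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.character(idx)) idx <- match(idx, gt$loci$name)
  genotype_table(gt$individuals, gt$loci[idx, , drop = FALSE],
                 gt$a1[, idx, drop = FALSE], gt$a2[, idx, drop = FALSE])
}

#' Allele-copy counts at one locus for a set of individuals
#'
#' Pairwise deletion: `NA` slots simply contribute no copy, so an
#' individual with one non-missing slot contributes a single copy.
#'
#' @param gt a [genotype_table()]
#' @param locus locus index or name
#' @param rows individual indices (default all)
#' @return named integer vector of allele counts (names = allele states)
#' @export
allele_counts <- function(gt, locus, rows = seq_len(nrow(gt$individuals))) {
  if (is.character(locus)) locus <- match(locus, gt$loci$name)
  x <- c(gt$a1[rows, locus], gt$a2[rows, locus])
  x <- x[!is.na(x)]
  if (!length(x)) return(integer(0))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

# allele counts split by species for a two-species table, as the
# alleles x 2 count matrix that the differentiation statistics expect
species_count_matrix <- function(gt, locus, species_a, species_b) {
  ra <- which(gt$individuals$species == species_a)
  rb <- which(gt$individuals$species == species_b)
  ca <- allele_counts(gt, locus, ra)
  cb <- allele_counts(gt, locus, rb)
  states <- sort(unique(as.integer(c(names(ca), names(cb)))))
  m <- cbind(a = ca[as.character(states)], b = cb[as.character(states)])
  m[is.na(m)] <- 0L
  rownames(m) <- states
  m
}

#' Randomly discard one allele per locus for inbred individuals
#'
#' Inbred isofemale lines are expected to be homozygous; residual
#' heterozygosity inflates diversity statistics. This correction keeps,
#' for every genotype of an inbred-flagged individual, a single uniformly
#' chosen allele copy (for homozygotes the choice is immaterial), leaving
#' non-inbred individuals untouched. Uses R's global RNG.
#'
#' @param gt a [genotype_table()]
#' @return a [genotype_table()] in which inbred individuals carry one
#'   allele copy per locus (`a2` slot `NA`)
#' @export
drop_inbred_alleles <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  rows <- which(gt$individuals$inbred)
  a1 <- gt$a1; a2 <- gt$a2
  for (i in rows) {
    for (j in seq_len(nrow(gt$loci))) {
      x <- c(a1[i, j], a2[i, j])
      x <- x[!is.na(x)]
      if (!length(x)) next
      a1[i, j] <- if (length(x) == 1L) x else x[sample.int(2L, 1L)]
      a2[i, j] <- NA_integer_
    }
  }
  genotype_table(gt$individuals, gt$loci, a1, a2)
}
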