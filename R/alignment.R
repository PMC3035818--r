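#' Labelled sequence alignment
#'
#' Container for an aligned set of DNA sequences with per-sequence species
#' and collection labels and an optional mask of "silent" columns used for
#' masked statistics (silent nucleotide diversity, silent divergence).
#'
#' Columns containing an alignment gap (`-`) or an ambiguous base (`N`) in
#' any sequence are recorded and excluded from every statistic, so that all
#' pairwise comparisons are made on the same set of sites ("after discarding
#' alignment gaps"). The excluded columns are kept in the object rather than
#' silently dropped.
#'
#' @param sequences character matrix of single residues (rows = sequences,
#'   must be named with sequence ids) over `A,C,G,T,-,N`, or a named
#'   character vector of equal-length residue strings.
#' @param meta data.frame with columns `id`, `species`, `collection`; one
#'   row per sequence. Extra columns are kept.
#' @param site_mask optional integer vector of 1-based column indices
#'   designating silent sites.
#' @return An object of class `"alignment"`: a list with elements `mat`
#'   (character matrix), `meta`, `length`, `site_mask`, `analysed` (integer
#'   vector of gap/N-free column indices), `excluded` (their complement).
#' @export
alignment <- function(sequences, meta, site_mask = NULL) {
  if (is.character(sequences) && is.null(dim(sequences))) {
    nch <- nchar(sequences)
    if (length(unique(nch)) != 1L)
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(nch), collapse = ", "), ")")
    ids <- names(sequences)
    if (is.null(ids)) stop("sequences must be named by id")
    sequences <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(sequences) <- ids
  }
  mat <- toupper(sequences)
  if (is.null(rownames(mat))) stop("sequence matrix must have row names (ids)")
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("alignment error: unexpected residues: ", paste(bad, collapse = " "))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("id", "species", "collection")
  if (!all(need %in% names(meta)))
    stop("metadata error: metadata must have columns ",
         paste(need, collapse = ", "))
  missing_ids <- setdiff(rownames(mat), meta$id)
  if (length(missing_ids))
    stop("metadata error: no metadata for id(s): ",
         paste(missing_ids, collapse = ", "))
  meta <- meta[match(rownames(mat), meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  L <- ncol(mat)
  if (!is.null(site_mask)) {
    site_mask <- sort(unique(as.integer(site_mask)))
    if (any(site_mask < 1L | site_mask > L))
      stop("site_mask indices out of range 1..", L)
  }
  has_gap <- apply(mat, 2L, function(col) any(col %in% c("-", "N")))
  structure(list(
    mat = mat, meta = meta, length = L, site_mask = site_mask,
    analysed = which(!has_gap), excluded = which(has_gap)
  ), class = "alignment")
}

#' Read a FASTA alignment with per-sequence metadata
#'
#' @param path path to an aligned FASTA file (equal-length records).
#' @param labels data.frame with columns `id`, `species`, `collection`, or
#'   the path of a CSV/TSV file with those columns. Every record id in the
#'   FASTA must have a metadata row.
#' @param site_mask optional 1-based silent-site column indices.
#' @return an [alignment()] object.
#' @export
read_alignment <- function(path, labels, site_mask = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("alignment error: FASTA records have unequal lengths")
  mat <- toupper(as.character(as.matrix(dna)))
  if (is.character(labels) && length(labels) == 1L) {
    sep <- if (grepl("\\.tsv$", labels)) "\t" else ","
    labels <- utils::read.table(labels, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
  }
  alignment(mat, labels, site_mask = site_mask)
}

#' Write an alignment to FASTA
#' @param aln an [alignment()] object
#' @param path output file path
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  seqs <- apply(aln$mat, 1L, paste0, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[i]), con)
  invisible(path)
}

#' Restrict an alignment to a subset of sequences
#' @param aln an [alignment()] object
#' @param ids sequence ids to keep
#' @return an [alignment()] on the same columns (analysed columns are
#'   recomputed: a gap column in a removed sequence may become analysable)
#' @export
subset_alignment <- function(aln, ids) {
  stopifnot(inherits(aln, "alignment"))
  miss <- setdiff(ids, rownames(aln$mat))
  if (length(miss)) stop("unknown sequence id(s): ", paste(miss, collapse = ", "))
  alignment(aln$mat[ids, , drop = FALSE],
            aln$meta[match(ids, aln$meta$id), , drop = FALSE],
            site_mask = aln$site_mask)
}

# Columns entering a statistic: gap/N-free, optionally intersected with the
# silent-site mask.
analysed_columns <- function(aln, mask_only = FALSE) {
  cols <- aln$analysed
  if (mask_only) {
    if (is.null(aln$site_mask))
      stop("mask_only = TRUE but the alignment has no site_mask")
    cols <- intersect(cols, aln$site_mask)
  }
  cols
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", nrow(x$mat), "sequences x", x$length, "columns;",
      length(x$analysed), "analysed,", length(x$excluded), "gap/N-excluded")
  if (!is.null(x$site_mask)) cat(";", length(x$site_mask), "masked (silent)")
  cat("\n")
  invisible(x)
}

#' Diversity summary of an alignment
#'
#' DnaSP-style summary: number of segregating sites S, haplotype number h,
#' haplotype diversity Hd, and nucleotide diversity both raw and with the
#' Jukes-Cantor multiple-hit correction.
#'
#' Hd uses the unbiased estimator `n (1 - sum p_i^2) / (n - 1)` over
#' haplotype frequencies; haplotypes are distinct strings over the analysed
#' columns. `pi_raw` is the mean over all sequence pairs of the per-site
#' proportion of differing analysed sites, and
#' `pi_jc = -(3/4) log(1 - (4/3) pi_raw)` applies the correction to the
#' mean (not pair by pair).
#'
#' @param aln an [alignment()] object with at least two sequences
#' @param mask_only if `TRUE`, restrict to silent (masked) columns
#' @return list of class `"diversity_summary"` with `n`, `S`, `h`, `Hd`,
#'   `pi_raw`, `pi_jc`, `analysed_sites`
#' @export
diversity_summary <- function(aln, mask_only = FALSE) {
  stopifnot(inherits(aln, "alignment"))
  n <- nrow(aln$mat)
  if (n < 2L) stop("sample-size error: need at least 2 sequences, got ", n)
  cols <- analysed_columns(aln, mask_only)
  sub <- aln$mat[, cols, drop = FALSE]
  S <- sum(apply(sub, 2L, function(col) length(unique(col)) > 1L))
  hap <- apply(sub, 1L, paste0, collapse = "")
  counts <- table(hap)
  h <- length(counts)
  p <- as.numeric(counts) / n
  Hd <- if (h == 1L) 0 else n * (1 - sum(p^2)) / (n - 1)
  pi_raw <- mean_pairwise_pdist(sub)
  structure(list(n = n, S = S, h = h, Hd = Hd,
                 pi_raw = pi_raw, pi_jc = jc_correct(pi_raw),
                 analysed_sites = length(cols)),
            class = "diversity_summary")
}

# mean over all C(n,2) pairs of per-site p-distance
mean_pairwise_pdist <- function(sub) {
  n <- nrow(sub)
  L <- ncol(sub)
  if (L == 0L) return(0)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + sum(sub[i, ] != sub[j, ])
  tot / choose(n, 2) / L
}

# Jukes-Cantor correction of a mean per-site p-distance
jc_correct <- function(p) {
  if (p >= 0.75)
    stop("Jukes-Cantor domain error: mean p-distance ", signif(p, 4),
         " >= 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("n=%d  S=%d  h=%d  Hd=%.4f  pi=%.5f  pi(JC)=%.5f  sites=%d\n",
              x$n, x$S, x$h, x$Hd, x$pi_raw, x$pi_jc, x$analysed_sites))
  invisible(x)
}

#' Fixed differences, shared polymorphisms and silent divergence between
#' two species
#'
#' `F` counts analysed columns where the base sets of the two species are
#' disjoint (fixed differences); `S_star` counts columns polymorphic within
#' both species that share at least two bases (shared polymorphisms); `Ks`
#' is the Jukes-Cantor corrected mean per-site difference over all
#' between-species sequence pairs, computed on the silent-site mask when
#' the alignment carries one.
#'
#' @param aln an [alignment()] object
#' @param species_a,species_b species labels present in `aln$meta$species`
#' @return list with elements `F`, `S_star`, `Ks`
#' @export
between_species_summary <- function(aln, species_a, species_b) {
  stopifnot(inherits(aln, "alignment"))
  ia <- which(aln$meta$species == species_a)
  ib <- which(aln$meta$species == species_b)
  if (!length(ia) || !length(ib))
    stop("sample-size error: species '",
         if (!length(ia)) species_a else species_b, "' has no sequences")
  cols <- analysed_columns(aln)
  A <- aln$mat[ia, cols, drop = FALSE]
  B <- aln$mat[ib, cols, drop = FALSE]
  Fcnt <- 0L
  Sstar <- 0L
  for (j in seq_along(cols)) {
    ua <- unique(A[, j]); ub <- unique(B[, j])
    if (!length(intersect(ua, ub))) Fcnt <- Fcnt + 1L
    else if (length(ua) >= 2L && length(ub) >= 2L &&
             length(intersect(ua, ub)) >= 2L) Sstar <- Sstar + 1L
  }
  kcols <- analysed_columns(aln, mask_only = !is.null(aln$site_mask))
  Am <- aln$mat[ia, kcols, drop = FALSE]
  Bm <- aln$mat[ib, kcols, drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(Am))) for (j in seq_len(nrow(Bm)))
    tot <- tot + sum(Am[i, ] != Bm[j, ])
  p <- tot / (nrow(Am) * nrow(Bm)) / length(kcols)
  list(F = Fcnt, S_star = Sstar, Ks = jc_correct(p))
}

# standard genetic code, third-position lookup built once
.GENETIC_CODE <- c(
  TTT="F", TTC="F", TTA="L", TTG="L", CTT="L", CTC="L", CTA="L", CTG="L",
  ATT="I", ATC="I", ATA="I", ATG="M", GTT="V", GTC="V", GTA="V", GTG="V",
  TCT="S", TCC="S", TCA="S", TCG="S", CCT="P", CCC="P", CCA="P", CCG="P",
  ACT="T", ACC="T", ACA="T", ACG="T", GCT="A", GCC="A", GCA="A", GCG="A",
  TAT="Y", TAC="Y", TAA="*", TAG="*", CAT="H", CAC="H", CAA="Q", CAG="Q",
  AAT="N", AAC="N", AAA="K", AAG="K", GAT="D", GAC="D", GAA="E", GAG="E",
  TGT="C", TGC="C", TGA="*", TGG="W", CGT="R", CGC="R", CGA="R", CGG="R",
  AGT="S", AGC="S", AGA="R", AGG="R", GGT="G", GGC="G", GGA="G", GGG="G")

# number of third-position bases synonymous with the given codon
third_pos_degeneracy <- function(codon) {
  aa <- .GENETIC_CODE[[codon]]
  fam <- .GENETIC_CODE[paste0(substr(codon, 1, 2), c("A", "C", "G", "T"))]
  sum(fam == aa)
}

#' Silent-site mask from coding frame
#'
#' Convenience classifier for coding alignments: returns the 1-based
#' indices of third-codon-position columns that are at least two-fold
#' degenerate for every codon observed in the alignment at that position
#' (codons containing a gap or N are ignored). Callers with their own
#' definition of silent sites may supply any mask directly to
#' [alignment()].
#'
#' @param aln an [alignment()] object of in-frame coding sequence
#' @param frame_offset 0-based offset of the first complete codon
#' @return integer vector of silent-site column indices
#' @export
silent_site_mask <- function(aln, frame_offset = 0L) {
  stopifnot(inherits(aln, "alignment"))
  if (aln$length < frame_offset + 3L)
    stop("frame error: alignment shorter than one codon at offset ",
         frame_offset)
  starts <- seq(frame_offset + 1L, aln$length - 2L, by = 3L)
  mask <- integer(0)
  n_codons <- 0L
  n_all_stop <- 0L
  for (s in starts) {
    cod <- apply(aln$mat[, s:(s + 2L), drop = FALSE], 1L, paste0,
                 collapse = "")
    cod <- cod[!grepl("[-N]", cod)]
    if (!length(cod)) next
    n_codons <- n_codons + 1L
    aas <- .GENETIC_CODE[cod]
    if (all(aas == "*") && s + 2L < aln$length) {
      n_all_stop <- n_all_stop + 1L
      next
    }
    if (all(vapply(unique(cod), third_pos_degeneracy, 0L) >= 2L))
      mask <- c(mask, s + 2L)
  }
  if (n_all_stop > 0L)
    stop("frame error: internal stop codon fixed in all sequences")
  mask
}

#' Tabulate diversity summaries by group
#'
#' One [diversity_summary()] row per group of sequences (typically species
#' or haplogroup), in the column order n, S, h, Hd, pi.
#'
#' @param aln an [alignment()] object
#' @param grouping named character vector or factor: group label per
#'   sequence id (names must be sequence ids); ids absent from `grouping`
#'   are skipped
#' @param mask_only restrict to silent columns
#' @return data.frame with columns group, n, S, h, Hd, pi_jc, pi_raw;
#'   groups with fewer than two sequences are skipped (the summary is
#'   undefined there)
#' @export
diversity_table <- function(aln, grouping, mask_only = FALSE) {
  grouping <- grouping[!is.na(grouping)]
  groups <- split(names(grouping), as.character(grouping))
  groups <- groups[lengths(groups) >= 2L]
  rows <- lapply(groups, function(ids) {
    d <- diversity_summary(subset_alignment(aln, ids), mask_only = mask_only)
    data.frame(n = d$n, S = d$S, h = d$h, Hd = d$Hd,
               pi_jc = d$pi_jc, pi_raw = d$pi_raw)
  })
  out <- do.call(rbind, rows)
  data.frame(group = rownames(out), out, row.names = NULL)
}
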