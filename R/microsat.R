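#' Random step signs for the stepwise mutation model
#'
#' Each infinite-sites mutation becomes a microsatellite repeat-number
#' change of one unit, gaining or losing a repeat with equal probability
#' (strict single-step SMM). Uses R's global RNG.
#'
#' @param site_count number of segregating sites at the locus
#' @return integer vector in \{+1, -1\} of length `site_count`
#' @export
assign_steps <- function(site_count) {
  if (site_count < 0 || site_count != round(site_count))
    stop("parameter error: site_count must be a nonnegative integer")
  if (site_count == 0L) return(integer(0))
  sample(c(-1L, 1L), site_count, replace = TRUE)
}

#' Convert infinite-sites haplotypes to microsatellite alleles
#'
#' The allele of chromosome c is `baseline + sum_s incidence[c, s] *
#' steps[s]`: each derived mutation carried contributes its +-1 step.
#' Distinct mutational paths may yield equal allele states (homoplasy),
#' which is the point of the conversion. All downstream differentiation
#' statistics are invariant to the baseline offset.
#'
#' @param locus a [drop_mutations()] result
#' @param steps step vector from [assign_steps()], one entry per site
#' @param baseline integer allele state of the mutation-free chromosome
#' @return object of class `"msat_locus_sample"`: list with `alleles`
#'   (integer per chromosome) and `deme_of`
#' @export
haplotypes_to_alleles <- function(locus, steps, baseline = 0L) {
  stopifnot(inherits(locus, "simulated_locus"))
  if (length(steps) != locus$site_count)
    stop("shape error: length(steps) = ", length(steps),
         " but locus has ", locus$site_count, " sites")
  alleles <- if (locus$site_count == 0L) rep(0L, nrow(locus$incidence))
             else as.integer(locus$incidence %*% steps)
  structure(list(alleles = alleles + as.integer(baseline),
                 deme_of = locus$tree$tip_deme),
            class = "msat_locus_sample")
}

#' Simulate one microsatellite locus under the isolation model
#'
#' Convenience chain: genealogy, infinite-sites mutations, SMM conversion.
#'
#' @param model an [isolation_model()]
#' @param baseline baseline allele state
#' @return an `"msat_locus_sample"`
#' @export
simulate_msat_locus <- function(model, baseline = 0L) {
  locus <- drop_mutations(simulate_genealogy(model), model$theta)
  haplotypes_to_alleles(locus, assign_steps(locus$site_count), baseline)
}

#' Allele counts per deme of a simulated microsatellite locus
#'
#' @param sample_ an `"msat_locus_sample"`
#' @return integer matrix, rows = allele states, two columns (demes)
#' @export
msat_deme_counts <- function(sample_) {
  stopifnot(inherits(sample_, "msat_locus_sample"))
  states <- sort(unique(sample_$alleles))
  cbind(deme1 = tabulate(match(sample_$alleles[sample_$deme_of == 1L], states),
                         length(states)),
        deme2 = tabulate(match(sample_$alleles[sample_$deme_of == 2L], states),
                         length(states)))
}
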