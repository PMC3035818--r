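#' Poisson divergence-time point estimate
#'
#' Given `k` observed silent substitutions between a haplotype pair over
#' `L` compared silent sites and a per-site per-year per-lineage silent
#' substitution rate `mu`, the expected number of substitutions after `T`
#' years of divergence is `lambda = 2 mu L T` (two lineages each
#' accumulating substitutions independently). The point estimate equates
#' the observation to its expectation:
#' `T = k / (2 mu L)`.
#'
#' @param k nonnegative integer, observed silent substitutions
#' @param L positive integer, silent sites compared
#' @param mu substitution rate per site per year per lineage
#' @return divergence time in years
#' @export
divergence_point_estimate <- function(k, L, mu) {
  check_dating_input(k, L, mu)
  k / (2 * mu * L)
}

#' Poisson upper bound on divergence time
#'
#' The largest divergence time still compatible, at level `alpha`, with
#' observing no more than `k` substitutions: the unique `lambda` with
#' `P(X <= k | lambda) = alpha` for `X ~ Poisson(lambda)`, found by
#' monotone bisection to `|d lambda| < 1e-9`, then converted to years via
#' `T = lambda / (2 mu L)`. For `k = 0` this reduces to the closed form
#' `lambda = -log(alpha)`.
#'
#' @inheritParams divergence_point_estimate
#' @param alpha one-sided significance level in (0, 1); default 0.05
#' @return list with `t_upper` (years) and `lambda_upper`
#' @export
divergence_upper_bound <- function(k, L, mu, alpha = 0.05) {
  check_dating_input(k, L, mu)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("parameter error: alpha must lie in (0, 1)")
  lo <- 0
  hi <- k + 50
  # ppois(k; lambda) decreases monotonically in lambda from 1 to 0
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (stats::ppois(k, mid) > alpha) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  list(t_upper = lambda / (2 * mu * L), lambda_upper = lambda)
}

check_dating_input <- function(k, L, mu) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k))
    stop("parameter error: k must be a nonnegative integer")
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("parameter error: L must be positive")
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("parameter error: mu must be positive")
  if (k > L) stop("parameter error: k cannot exceed L")
  invisible(TRUE)
}

#' Silent-site differences to the closest donor haplotype
#'
#' For each recipient sequence, counts differences over the silent-site
#' mask to every sequence of the donor species and reports the minimum,
#' together with all donors attaining it.
#'
#' @param aln an [alignment()] object carrying a `site_mask`
#' @param donor_species species label of the candidate donors
#' @param recipient_ids ids of the putatively introgressed sequences
#' @return data.frame with columns `recipient`, `donor`, `k`; recipients
#'   with tied nearest donors occupy several rows
#' @export
closest_pair_differences <- function(aln, donor_species, recipient_ids) {
  stopifnot(inherits(aln, "alignment"))
  if (is.null(aln$site_mask)) stop("alignment has no site_mask")
  donors <- aln$meta$id[aln$meta$species == donor_species]
  donors <- setdiff(donors, recipient_ids)
  if (!length(donors))
    stop("sample-size error: no sequences for donor species '",
         donor_species, "'")
  cols <- analysed_columns(aln, mask_only = TRUE)
  sub <- aln$mat[, cols, drop = FALSE]
  out <- lapply(recipient_ids, function(r) {
    if (!r %in% rownames(sub)) stop("unknown recipient id: ", r)
    d <- vapply(donors, function(dn) sum(sub[r, ] != sub[dn, ]), 0)
    kmin <- min(d)
    data.frame(recipient = r, donor = donors[d == kmin], k = kmin,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Probability that a haplotype at frequency p is absent from a sample
#'
#' The binomial probability of zero successes in `n` independent draws
#' with success probability `p_hat`: `(1 - p_hat)^n`. Used to ask whether
#' earlier surveys could plausibly have missed a haplotype observed at
#' frequency `p_hat` in the present collections.
#'
#' @param p_hat observed haplotype frequency, strictly in (0, 1)
#' @param n sample size of the survey that did not observe it
#' @return the non-sampling probability
#' @export
prob_unsampled_haplotype <- function(p_hat, n) {
  if (!is.numeric(p_hat) || length(p_hat) != 1L || p_hat <= 0 || p_hat >= 1)
    stop("parameter error: p_hat must lie strictly in (0, 1)")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("parameter error: n must be a positive integer")
  (1 - p_hat)^n
}

#' Date every recipient haplotype against a donor species
#'
#' Convenience wrapper: runs [closest_pair_differences()] and applies the
#' Poisson point estimate and upper bound to each recipient's minimum
#' substitution count.
#'
#' @inheritParams closest_pair_differences
#' @param mu silent substitution rate per site per year per lineage
#' @param alpha one-sided level for the upper bound
#' @param L number of silent sites; defaults to the number of analysed
#'   masked columns of `aln`
#' @return data.frame: recipient, donor, k, t_mean, t_upper, lambda_upper
#' @export
date_introgression <- function(aln, donor_species, recipient_ids,
                               mu, alpha = 0.05, L = NULL) {
  cp <- closest_pair_differences(aln, donor_species, recipient_ids)
  if (is.null(L)) L <- length(analysed_columns(aln, mask_only = TRUE))
  cp$t_mean <- vapply(cp$k, divergence_point_estimate, 0, L = L, mu = mu)
  ub <- lapply(cp$k, divergence_upper_bound, L = L, mu = mu, alpha = alpha)
  cp$t_upper <- vapply(ub, `[[`, 0, "t_upper")
  cp$lambda_upper <- vapply(ub, `[[`, 0, "lambda_upper")
  cp
}
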