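#' Simulated null distribution of a differentiation statistic
#'
#' For each replicate, one locus is simulated under the isolation model
#' (genealogy, infinite-sites mutations, stepwise-mutation-model
#' conversion) and the chosen statistic is computed between the two
#' demes' allele counts. Monomorphic replicates, on which the statistic
#' is undefined, are recorded as `NA` and excluded from the percentile
#' cutoffs; their rate is reported.
#'
#' Tail conventions: `"central95"` places 2.5% of the simulated mass in
#' each tail (5% total outlier rate, the default); `"tail5"` places 5%
#' in each tail. Cutoffs are inverse-ECDF (type-1) order statistics, so a
#' rerun with the same seed reproduces them exactly.
#'
#' @param model an [isolation_model()]
#' @param replicates number of simulated loci (>= 100; the reference
#'   analysis uses 10 000)
#' @param statistic `"fst"` or `"gst_prime"`
#' @param tail_mode `"central95"` or `"tail5"`
#' @return object of class `"null_distribution"`: list with `values`
#'   (length `replicates`, `NA` where undefined), `cutoffs`
#'   (`lower`/`upper`), `statistic`, `tail_mode`, `model`,
#'   `n_undefined`
#' @export
build_null <- function(model, replicates, statistic = c("fst", "gst_prime"),
                       tail_mode = c("central95", "tail5")) {
  stopifnot(inherits(model, "isolation_model"))
  if (replicates < 100) stop("parameter error: need >= 100 replicates")
  statistic <- match.arg(statistic)
  tail_mode <- match.arg(tail_mode)
  stat_fun <- if (statistic == "fst") fst_wc else gst_prime
  values <- vapply(seq_len(replicates), function(i) {
    cnt <- msat_deme_counts(simulate_msat_locus(model))
    if (nrow(cnt) < 2L) NA_real_ else stat_fun(cnt)
  }, 0)
  n_undef <- sum(is.na(values))
  if (n_undef > replicates / 2)
    stop("model error: statistic undefined on ", n_undef, "/", replicates,
         " replicates")
  structure(list(values = values, cutoffs = null_cutoffs(values, tail_mode),
                 statistic = statistic, tail_mode = tail_mode, model = model,
                 n_undefined = n_undef),
            class = "null_distribution")
}

null_cutoffs <- function(values, tail_mode) {
  m <- if (tail_mode == "central95") 0.025 else 0.05
  q <- stats::quantile(values[!is.na(values)], c(m, 1 - m), type = 1,
                       names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "null distribution of %s: %d replicates (%d undefined), %s cutoffs [%.4f, %.4f]\n",
    x$statistic, length(x$values), x$n_undefined, x$tail_mode,
    x$cutoffs["lower"], x$cutoffs["upper"]))
  print(x$model)
  invisible(x)
}

#' Classify observed loci against a simulated null
#'
#' A locus is `low` if its statistic falls below the lower cutoff, `high`
#' above the upper cutoff, `none` otherwise; loci whose statistic is
#' undefined (e.g. fixed for the same allele in both species) are flagged
#' `undefined` and excluded from the outlier counts.
#'
#' @param observed data.frame from [locus_stats()] (or any data.frame
#'   with a `locus` column and a column named after the null's statistic)
#' @param null a [build_null()] result
#' @return object of class `"outlier_report"`: list with `calls`
#'   (data.frame locus, value, call), `n_low`, `n_high`, `n_none`,
#'   `n_undefined`, `cutoffs`, `model`, `statistic`, `tail_mode`
#' @export
classify_loci <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  observed <- as.data.frame(observed)
  if (!nrow(observed)) stop("usage error: no observed loci")
  if (!null$statistic %in% names(observed))
    stop("usage error: observed loci carry no '", null$statistic,
         "' column (null built for a different statistic?)")
  value <- observed[[null$statistic]]
  call <- ifelse(is.na(value), "undefined",
                 ifelse(value < null$cutoffs["lower"], "low",
                        ifelse(value > null$cutoffs["upper"], "high",
                               "none")))
  calls <- data.frame(
    locus = if ("locus" %in% names(observed)) observed$locus
            else seq_len(nrow(observed)),
    value = value, call = call)
  structure(list(calls = calls,
                 n_low = sum(call == "low"), n_high = sum(call == "high"),
                 n_none = sum(call == "none"),
                 n_undefined = sum(call == "undefined"),
                 cutoffs = null$cutoffs, model = null$model,
                 statistic = null$statistic, tail_mode = null$tail_mode),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "outlier scan (%s, %s, tau=%g): %d low, %d high, %d none, %d undefined\n",
    x$statistic, x$tail_mode, x$model$tau,
    x$n_low, x$n_high, x$n_none, x$n_undefined))
  invisible(x)
}

#' Outlier scan across a grid of split times
#'
#' Rebuilds the null and reclassifies the same observed loci at each
#' `tau` of the grid — the sensitivity analysis for uncertainty in the
#' species divergence time.
#'
#' @inheritParams classify_loci
#' @param model an [isolation_model()] whose `tau` is replaced per grid
#'   point
#' @param tau_grid nonempty numeric vector of split times (4*N0 units)
#' @param replicates simulated loci per null
#' @param statistic,tail_mode as in [build_null()]
#' @return object of class `"sensitivity_scan"`: list with `reports`
#'   (one [classify_loci()] report per tau, named by tau) and `summary`
#'   (data.frame tau, n_low, n_high, n_none, n_undefined)
#' @export
sensitivity_rescan <- function(observed, model, tau_grid, replicates,
                               statistic = c("fst", "gst_prime"),
                               tail_mode = c("central95", "tail5")) {
  if (!length(tau_grid)) stop("usage error: empty tau grid")
  statistic <- match.arg(statistic)
  tail_mode <- match.arg(tail_mode)
  reports <- lapply(tau_grid, function(tau) {
    m <- isolation_model(model$n1, model$n2, model$theta, tau)
    classify_loci(observed, build_null(m, replicates, statistic, tail_mode))
  })
  names(reports) <- as.character(tau_grid)
  summary <- data.frame(
    tau = tau_grid,
    n_low = vapply(reports, `[[`, 0L, "n_low"),
    n_high = vapply(reports, `[[`, 0L, "n_high"),
    n_none = vapply(reports, `[[`, 0L, "n_none"),
    n_undefined = vapply(reports, `[[`, 0L, "n_undefined"),
    row.names = NULL)
  structure(list(reports = reports, summary = summary),
            class = "sensitivity_scan")
}
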