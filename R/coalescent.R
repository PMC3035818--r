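#' Two-population isolation model
#'
#' Parameters of a neutral isolation (no-migration) model for a single
#' non-recombining locus, in Hudson's `ms` conventions: time in units of
#' 4*N0 generations, theta = 4*N0*mu per locus, demes of constant size N0
#' before and after the join. `n1` and `n2` chromosomes are sampled from
#' demes 1 and 2; looking backwards in time the demes merge into one pool
#' at time `tau`.
#'
#' @param n1,n2 chromosomes sampled per deme (`n1 + n2 >= 2`; one of the
#'   two may be 0)
#' @param theta per-locus scaled mutation rate 4*N0*mu
#' @param tau population-join time in units of 4*N0 generations
#' @return object of class `"isolation_model"`
#' @export
isolation_model <- function(n1, n2, theta, tau) {
  if (n1 < 0 || n2 < 0 || n1 + n2 < 2)
    stop("parameter error: need n1 + n2 >= 2 sampled chromosomes")
  if (theta <= 0) stop("parameter error: theta must be positive")
  if (tau < 0) stop("parameter error: tau must be nonnegative")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 theta = theta, tau = tau),
            class = "isolation_model")
}

#' @export
print.isolation_model <- function(x, ...) {
  cat(sprintf("isolation model: n1=%d n2=%d theta=%g tau=%g (4N0 units)\n",
              x$n1, x$n2, x$theta, x$tau))
  invisible(x)
}

#' Convert a divergence time in years to coalescent units
#'
#' `tau = t_years * gens_per_year / (4 * N0)` — e.g. 250 000 years at ten
#' generations per year and diploid N0 = 1e6 gives tau = 0.625.
#'
#' @param t_years divergence time in years
#' @param N0 diploid effective population size
#' @param gens_per_year generations per year
#' @return tau in units of 4*N0 generations
#' @export
years_to_tau <- function(t_years, N0, gens_per_year) {
  if (t_years < 0 || N0 <= 0 || gens_per_year <= 0)
    stop("parameter error: t_years must be >= 0 and N0, gens_per_year > 0")
  t_years * gens_per_year / (4 * N0)
}

#' Simulate a genealogy under the isolation model
#'
#' Standard n-coalescent run backwards in time: before `tau`, lineages
#' coalesce only within their deme, each deme at total rate j(j-1) per
#' unit of 4*N0 generations when it holds j lineages (so a single pair
#' coalesces at rate 2, giving E[T2] = 1/2); at `tau` the remaining
#' lineages merge into one pool and coalescence continues to a single
#' root. Pairs are chosen uniformly. Uses R's global RNG; call
#' [set.seed()] for reproducibility.
#'
#' @param model an [isolation_model()]
#' @return object of class `"genealogy"`: list with `parent` (parent index
#'   per node, 0 at the root), `node_time` (node heights, 4*N0 units),
#'   `n_tips`, `tip_deme` (1/2 per tip), `tmrca`, `branch_length` (branch
#'   above each non-root node), `total_length`
#' @export
simulate_genealogy <- function(model) {
  stopifnot(inherits(model, "isolation_model"))
  n1 <- model$n1; n2 <- model$n2; tau <- model$tau
  n <- n1 + n2
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  act1 <- seq_len(n1)
  act2 <- if (n2 > 0L) n1 + seq_len(n2) else integer(0)
  t <- 0
  nxt <- n + 1L
  merged <- tau <= 0
  if (merged) { act1 <- c(act1, act2); act2 <- integer(0) }
  repeat {
    k1 <- length(act1); k2 <- length(act2)
    r1 <- k1 * (k1 - 1); r2 <- k2 * (k2 - 1)
    R <- r1 + r2
    if (R == 0) {
      # one lineage per deme: nothing can happen until the join
      if (merged) break
      t <- tau; merged <- TRUE
      act1 <- c(act1, act2); act2 <- integer(0)
      next
    }
    dt <- stats::rexp(1L, R)
    if (!merged && t + dt >= tau) {
      t <- tau; merged <- TRUE
      act1 <- c(act1, act2); act2 <- integer(0)
      next
    }
    t <- t + dt
    if (r2 > 0 && stats::runif(1L) < r2 / R) {
      i <- sample.int(k2, 2L)
      pair <- act2[i]
      act2 <- c(act2[-i], nxt)
    } else {
      i <- sample.int(k1, 2L)
      pair <- act1[i]
      act1 <- c(act1[-i], nxt)
    }
    parent[pair] <- nxt
    node_time[nxt] <- t
    nxt <- nxt + 1L
    if (k1 + k2 == 2L && merged) break
  }
  nonroot <- seq_len(n_nodes - 1L)
  blen <- node_time[parent[nonroot]] - node_time[nonroot]
  structure(list(parent = parent, node_time = node_time, n_tips = n,
                 tip_deme = rep(c(1L, 2L), c(n1, n2)),
                 tmrca = node_time[n_nodes],
                 branch_length = blen,
                 total_length = sum(blen)),
            class = "genealogy")
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' The number of segregating sites is Poisson with mean
#' `theta * total branch length` (lengths in 4*N0 units, so that
#' E[S] = theta * a_(n-1), Watterson's expectation); each mutation falls
#' on a branch with probability proportional to its length and marks the
#' subtended tips as carrying the derived allele. Every mutation hits a
#' new site, so each site's derived set is exactly one clade.
#'
#' @param tree a [simulate_genealogy()] result
#' @param theta per-locus scaled mutation rate
#' @return object of class `"simulated_locus"`: list with `tree`,
#'   `site_count`, `incidence` (tips x sites 0/1 matrix), `tmrca`,
#'   `mut_node` (the node under each mutated branch)
#' @export
drop_mutations <- function(tree, theta) {
  stopifnot(inherits(tree, "genealogy"))
  if (theta <= 0) stop("parameter error: theta must be positive")
  n <- tree$n_tips
  S <- stats::rpois(1L, theta * tree$total_length)
  if (S == 0L) {
    inc <- matrix(0L, nrow = n, ncol = 0L)
    return(structure(list(tree = tree, site_count = 0L, incidence = inc,
                          tmrca = tree$tmrca, mut_node = integer(0)),
                     class = "simulated_locus"))
  }
  branch_node <- sample.int(2L * n - 2L, S, replace = TRUE,
                            prob = tree$branch_length)
  tips_below <- descendant_tips(tree)
  inc <- matrix(0L, nrow = n, ncol = S)
  for (s in seq_len(S)) inc[tips_below[[branch_node[s]]], s] <- 1L
  structure(list(tree = tree, site_count = S, incidence = inc,
                 tmrca = tree$tmrca, mut_node = branch_node),
            class = "simulated_locus")
}

# list of tip index vectors below each node (tips map to themselves);
# nodes are numbered in coalescence order, so one ascending pass suffices
descendant_tips <- function(tree) {
  n <- tree$n_tips
  n_nodes <- 2L * n - 1L
  below <- vector("list", n_nodes)
  below[seq_len(n)] <- as.list(seq_len(n))
  kids <- split(seq_len(n_nodes - 1L), tree$parent[seq_len(n_nodes - 1L)])
  for (v in (n + 1L):n_nodes) {
    ch <- kids[[as.character(v)]]
    below[[v]] <- c(below[[ch[1L]]], below[[ch[2L]]])
  }
  below
}

#' Simulate a batch of loci under an isolation model
#'
#' @param model an [isolation_model()]
#' @param replicates number of independent loci
#' @return list of `"simulated_locus"` objects
#' @export
simulate_loci <- function(model, replicates) {
  stopifnot(replicates >= 1)
  lapply(seq_len(replicates), function(i)
    drop_mutations(simulate_genealogy(model), model$theta))
}
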