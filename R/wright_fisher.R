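# Finite-population Wright-Fisher dynamics: the stochastic counterpart of
# the deterministic generation map, used to probe when the infinite-
# population theory applies. The controlling parameter is the
# population-wide mutation rate N * mu * L: far below 1 the population is
# essentially monomorphic and performs a neutral random walk on the viable
# network (robustness ~ the uniform baseline m0); far above 1 it tracks the
# deterministic stationary state.

# multinomial resampling fused with selection: probabilities proportional
# to w * counts
.wf_select <- function(counts, w, N) {
  probs <- w * counts
  s <- sum(probs)
  if (s <= 0) return(NULL)  # all-lethal, handled by caller
  as.vector(stats::rmultinom(1, N, probs))
}

# exact per-locus mutation of a counts vector using the dense kernel column
.wf_mutate_counts <- function(counts, Ucols) {
  occupied <- which(counts > 0L)
  out <- integer(length(counts))
  for (g in occupied) {
    out <- out + as.vector(stats::rmultinom(1, counts[g], Ucols[, g]))
  }
  out
}

# per-individual mutation for the individual-based path: flips each locus
# independently with probability mu
.wf_mutate_individuals <- function(geno, mu, L) {
  N <- length(geno)
  nflips <- stats::rbinom(1, N * L, mu)
  if (nflips == 0) return(geno)
  hit <- sample.int(N * L, nflips)
  ind <- (hit - 1L) %/% L + 1L
  locus <- (hit - 1L) %% L
  for (j in seq_len(nflips)) geno[ind[j]] <- bitwXor(geno[ind[j]], 2L^locus[j])
  geno
}

# one recombination round on an individual genotype vector
.wf_recombine_individuals <- function(geno, kind, r, L) {
  N <- length(geno)
  perm <- sample.int(N)
  npair <- N %/% 2L
  out <- geno
  if (npair == 0) return(out)
  i1 <- perm[seq_len(npair)]
  i2 <- perm[npair + seq_len(npair)]
  do_rec1 <- stats::runif(npair) < r
  do_rec2 <- stats::runif(npair) < r
  if (kind == "uniform") {
    mask <- sample.int(2L^L, npair, replace = TRUE) - 1L
  } else {
    cut <- sample.int(L - 1L, npair, replace = TRUE)
    mask <- 2L^cut - 1L  # prefix loci 1..cut
  }
  k <- geno[i1]; t <- geno[i2]
  child1 <- bitwOr(bitwAnd(k, mask), bitwAnd(t, bitwNot(mask) %% 2L^L))
  child2 <- bitwOr(bitwAnd(t, mask), bitwAnd(k, bitwNot(mask) %% 2L^L))
  out[i1] <- ifelse(do_rec1, child1, k)
  out[i2] <- ifelse(do_rec2, child2, t)
  out
}

.counts_to_individuals <- function(counts) rep.int(seq_along(counts) - 1L, counts)

.individuals_to_counts <- function(geno, n) tabulate(geno + 1L, nbins = n)

#' Wright-Fisher simulation on a fitness landscape
#'
#' Simulates `N` haploid individuals with non-overlapping generations. Each
#' generation consists of (i) fused selection and resampling (multinomial
#' with weights proportional to fitness times counts), (ii) independent
#' symmetric per-locus mutation at rate `mu`, and (iii) recombination:
#' random pairing without replacement for uniform/one-point crossover, each
#' pair contributing two offspring (one per parent order), each offspring
#' being a recombinant with probability `r` and a parental clone otherwise;
#' for the communal scheme each individual independently, with probability
#' `r`, redraws every locus from the post-mutation allele frequencies of
#' the whole population. Robustness is recorded each generation as
#' `sum(m_sigma * n_sigma) / N` over viable individuals and averaged over
#' the post-burn-in window and replicates. Generations in which the whole
#' population becomes lethal are restarted from the last viable composition
#' and counted.
#'
#' @param land a [fitness_landscape()] with at least one viable genotype.
#' @param N population size (held exactly constant).
#' @param mu per-locus mutation rate.
#' @param scheme a [recombination_scheme()].
#' @param generations sampled generations per replicate (after burn-in).
#' @param burnin discarded generations per replicate; default
#'   `min(ceiling(10 / mu), 1e5)` (about ten expected substitutions, capped).
#' @param reps independent replicates.
#' @param seed RNG seed; fixed seed gives bit-identical trajectories.
#' @param init `"uniform_viable"` (default: individuals drawn uniformly
#'   from the viable set) or a counts vector of length `2^L` summing to `N`.
#' @return list with `m` (grand mean robustness), `se` (standard error over
#'   replicate means for `reps > 1`, else over 10 batches), `m_rep`
#'   (per-replicate means), `restarts` (all-lethal restarts),
#'   `final_counts` (genotype counts at the end of the last replicate,
#'   summing to `N`), and the call parameters `N`, `mu`, `scheme`,
#'   `generations`, `burnin`.
#' @export
wf_simulate <- function(land, N, mu, scheme, generations,
                        burnin = NULL, reps = 1, seed = 1,
                        init = "uniform_viable") {
  .check_landscape(land)
  .check_scheme(scheme)
  .check_prob(mu, "mu")
  if (N < 1 || N != floor(N)) stop("'N' must be a positive integer", call. = FALSE)
  if (generations < 1) stop("'generations' must be positive", call. = FALSE)
  if (is.null(burnin)) burnin <- if (mu > 0) min(ceiling(10 / mu), 1e5) else 1000L
  L <- land$L
  n <- 2^L
  w <- land$w
  viable <- w > 0
  if (!any(viable)) stop("landscape has no viable genotype", call. = FALSE)
  m_sigma <- genotype_robustness(land)
  m_contrib <- ifelse(viable, m_sigma, 0)
  r <- scheme$r
  kind <- scheme$kind
  pairwise <- kind %in% c("uniform", "one_point") && r > 0
  if (pairwise && kind == "one_point" && L < 2)
    stop("one-point crossover requires L >= 2", call. = FALSE)
  if (L > 12) stop("Wright-Fisher simulation supported for L <= 12", call. = FALSE)
  Ucols <- mutation_matrix(L, mu)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  total_gens <- burnin + generations
  m_rep <- numeric(reps)
  restarts <- 0L
  batch_means <- NULL
  for (rep_i in seq_len(reps)) {
    counts <- if (identical(init, "uniform_viable")) {
      as.vector(stats::rmultinom(1, N, as.numeric(viable)))
    } else {
      if (length(init) != n || sum(init) != N)
        stop("'init' counts must have length 2^L and sum to N", call. = FALSE)
      as.integer(init)
    }
    last_viable <- counts
    m_trace <- numeric(generations)
    for (gen in seq_len(total_gens)) {
      sel <- .wf_select(counts, w, N)
      if (is.null(sel)) {
        restarts <- restarts + 1L
        counts <- last_viable
        sel <- .wf_select(counts, w, N)
        if (is.null(sel)) stop("cannot restart: stored composition is lethal",
                               call. = FALSE)
      }
      counts <- sel
      counts <- if (pairwise) {
        geno <- .counts_to_individuals(counts)
        geno <- .wf_mutate_individuals(geno, mu, L)
        geno <- .wf_recombine_individuals(geno, kind, r, L)
        .individuals_to_counts(geno, n)
      } else .wf_mutate_counts(counts, Ucols)
      if (!pairwise && kind == "communal" && r > 0) {
        # each individual independently resamples all loci from the pool
        keep <- stats::rbinom(n, counts, 1 - r)
        n_rec <- N - sum(keep)
        if (n_rec > 0) {
          q <- .le_projection(counts / N, L)
          keep <- keep + as.vector(stats::rmultinom(1, n_rec, q))
        }
        counts <- keep
      }
      if (any(counts[viable] > 0L)) last_viable <- counts
      if (gen > burnin)
        m_trace[gen - burnin] <- sum(m_contrib * counts) / N
    }
    m_rep[rep_i] <- mean(m_trace)
    if (reps == 1) {
      nb <- 10L
      batch <- split(m_trace, cut(seq_along(m_trace), nb, labels = FALSE))
      batch_means <- vapply(batch, mean, numeric(1))
    }
  }
  se <- if (reps > 1) stats::sd(m_rep) / sqrt(reps)
        else stats::sd(batch_means) / sqrt(length(batch_means))
  list(m = mean(m_rep), se = se, m_rep = m_rep, restarts = restarts,
       final_counts = counts, N = N, mu = mu, scheme = scheme,
       generations = generations, burnin = burnin)
}
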