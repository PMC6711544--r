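# Fitness-landscape generators and robustness statistics.
#
# A landscape is a fitness value w in [0,1] for each of the 2^L genotypes.
# Neutral models are two-level: viable (w = 1) or lethal (w = 0). The viable
# set V is {sigma : w > 0}; for neutral landscapes this coincides with
# {w == 1}.

#' Construct a fitness landscape object
#'
#' @param w numeric vector of length `2^L` with fitness values in `[0, 1]`,
#'   indexed by genotype (index 0 first).
#' @param L number of loci.
#' @param model model name stored as metadata.
#' @param params list of generator parameters stored as metadata.
#' @param seed RNG seed used by the generator, or `NA`.
#' @return an object of class `fitness_landscape`: a list with elements `L`,
#'   `w`, `model`, `params`, `seed`.
#' @export
fitness_landscape <- function(w, L, model = "custom", params = list(), seed = NA) {
  L <- .check_L(L)
  if (length(w) != 2^L) stop("'w' must have length 2^L", call. = FALSE)
  if (any(is.na(w)) || any(w < 0) || any(w > 1))
    stop("fitness values must lie in [0, 1]", call. = FALSE)
  structure(list(L = L, w = as.numeric(w), model = model,
                 params = params, seed = seed),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  nv <- sum(x$w > 0)
  cat(sprintf("Fitness landscape '%s': L = %d, %d of %d genotypes viable\n",
              x$model, x$L, nv, 2^x$L))
  if (!is.null(x$params) && length(x$params))
    cat("  parameters:", paste(names(x$params), unlist(x$params),
                               sep = "=", collapse = ", "), "\n")
  if (!is.na(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

.check_landscape <- function(land) {
  if (!inherits(land, "fitness_landscape"))
    stop("expected a 'fitness_landscape' object", call. = FALSE)
  land
}

#' Is the landscape two-level (neutral)?
#' @param land a [fitness_landscape()].
#' @return logical.
#' @export
is_neutral <- function(land) all(land$w %in% c(0, 1))

#' Mesa landscape
#'
#' Two-level landscape in which all genotypes within `k` point mutations of
#' the wild type (the all-zero genotype) are viable and all others lethal.
#' `k` is the mesa width, the critical Hamming distance of the plateau.
#'
#' @param L number of loci.
#' @param k critical Hamming distance, `0 <= k <= L`.
#' @return a [fitness_landscape()].
#' @examples
#' make_mesa(2, 1)$w  # c(1, 1, 1, 0): the double mutant is lethal
#' @export
make_mesa <- function(L, k) {
  L <- .check_L(L)
  if (k < 0 || k > L || k != floor(k)) stop("'k' must be in 0..L", call. = FALSE)
  w <- as.numeric(.popcounts(L) <= k)
  fitness_landscape(w, L, model = "mesa", params = list(k = as.integer(k)))
}

#' Percolation (holey) landscape
#'
#' Each genotype is independently viable with probability `p`. Landscapes
#' with no viable genotype are legal objects (they enter ensemble averages)
#' but are rejected by the dynamics solvers.
#'
#' @param L number of loci.
#' @param p viability probability.
#' @param seed RNG seed; the same seed reproduces the same landscape.
#' @return a [fitness_landscape()].
#' @export
make_percolation <- function(L, p, seed) {
  L <- .check_L(L)
  .check_prob(p, "p")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- as.numeric(stats::runif(2^L) < p)
  fitness_landscape(w, L, model = "percolation", params = list(p = p), seed = seed)
}

# save/restore the global RNG state so generators are reproducible without
# clobbering the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Sea-cliff landscape
#'
#' Distance-dependent random two-level landscape: genotype `sigma` is viable
#' with respect to a reference `kappa*` iff an independent Gaussian threshold
#' variable `eta ~ N(c, s^2)` exceeds the Hamming distance `d(sigma, kappa*)`.
#' With several references a genotype is viable iff it is viable with respect
#' to at least one of them (an independent `eta` is drawn per
#' genotype-reference pair). The mean and standard deviation are fixed by two
#' distances `d_lt < d_gt` at which the expected viability equals 0.99 and
#' 0.01: `c = (d_lt + d_gt)/2`, `s = 0.215 * (d_gt - d_lt)`.
#'
#' In the limit `d_gt - d_lt -> 0` with `k < c < k + 1` the model degenerates
#' to the mesa landscape of width `k`; in the opposite limit of very wide
#' cliffs it approaches an isotropic percolation landscape.
#'
#' @param L number of loci.
#' @param refs integer vector of reference genotype indices.
#' @param d_lt,d_gt distances at which mean viability is 0.99 and 0.01
#'   (`d_lt < d_gt`).
#' @param seed RNG seed.
#' @return a [fitness_landscape()]; the fitted `c` and `s` are stored in
#'   `$params`.
#' @export
make_seacliff <- function(L, refs, d_lt, d_gt, seed) {
  L <- .check_L(L)
  if (length(refs) < 1) stop("need at least one reference genotype", call. = FALSE)
  refs <- .check_genotype(refs, L)
  if (!(d_lt < d_gt)) stop("'d_lt' must be smaller than 'd_gt'", call. = FALSE)
  cc <- (d_lt + d_gt) / 2
  ss <- 0.215 * (d_gt - d_lt)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- 0:(2^L - 1L)
  viable <- rep(FALSE, 2^L)
  for (ref in refs) {
    d <- bit_count(bitwXor(idx, ref))
    eta <- stats::rnorm(2^L, mean = cc, sd = ss)
    viable <- viable | (eta > d)
  }
  fitness_landscape(as.numeric(viable), L, model = "seacliff",
                    params = list(refs = refs, d_lt = d_lt, d_gt = d_gt,
                                  c = cc, s = ss),
                    seed = seed)
}

#' Expected viability profile of the sea-cliff model
#'
#' Mean single-reference viability at Hamming distance `d` from the
#' reference: `(1 - erf((d - c) / (s * sqrt(2)))) / 2`.
#'
#' @param d Hamming distance (vectorized).
#' @param d_lt,d_gt calibration distances, as in [make_seacliff()].
#' @return expected fraction of viable genotypes at distance `d`.
#' @export
seacliff_profile <- function(d, d_lt, d_gt) {
  cc <- (d_lt + d_gt) / 2
  ss <- 0.215 * (d_gt - d_lt)
  stats::pnorm(d, mean = cc, sd = ss, lower.tail = FALSE)
}

#' Atoll landscape
#'
#' Ring-shaped neutral landscape: genotypes are viable iff their Hamming
#' distance to the wild type lies in `[inner, outer]`. With `inner = 0` this
#' is the mesa landscape of width `outer`. The atoll decouples robustness
#' from recombination weight: the recombination center can sit on the lethal
#' wild type inside the ring.
#'
#' @param L number of loci.
#' @param inner,outer inner and outer critical radii, `0 <= inner <= outer <= L`.
#' @return a [fitness_landscape()].
#' @export
make_atoll <- function(L, inner, outer) {
  L <- .check_L(L)
  if (inner < 0 || outer > L || inner > outer)
    stop("need 0 <= inner <= outer <= L", call. = FALSE)
  d <- .popcounts(L)
  w <- as.numeric(d >= inner & d <= outer)
  fitness_landscape(w, L, model = "atoll",
                    params = list(inner = as.integer(inner),
                                  outer = as.integer(outer)))
}

#' Mutational robustness of genotypes
#'
#' The robustness of a genotype is the fraction `m_sigma = n_sigma / L` of
#' its `L` point mutations that lead to a viable genotype. A neighbour counts
#' as viable iff its fitness is positive (for neutral landscapes this is
#' exactly `w == 1`). Robustness is defined for every genotype, viable or
#' lethal; population-level robustness ([population_robustness()]) weights
#' only the viable ones.
#'
#' @param land a [fitness_landscape()].
#' @param sigma optional genotype index vector; default all genotypes.
#' @return numeric vector of robustness values in `[0, 1]`.
#' @export
genotype_robustness <- function(land, sigma = NULL) {
  .check_landscape(land)
  L <- land$L
  viable <- land$w > 0
  flips <- .flip_table(L)
  n <- rep(0L, 2^L)
  for (i in seq_len(L)) n <- n + viable[flips[, i]]
  m <- n / L
  if (is.null(sigma)) m else m[.check_genotype(sigma, L) + 1L]
}

#' Robustness of a uniform population on the mesa landscape
#'
#' Exact robustness of a population distributed uniformly over the viable
#' plateau `d <= k`:
#' `m0 = (C(L,k) * k/L + sum_{i<k} C(L,i)) / sum_{i<=k} C(L,i)`.
#' For large `L` this approaches `min(2k/L, 1)`, returned with
#' `approx = TRUE`.
#'
#' @param L number of loci.
#' @param k mesa width.
#' @param approx if `TRUE` return the large-`L` approximation instead of the
#'   exact value.
#' @return robustness in `[0, 1]`.
#' @examples
#' uniform_robustness_mesa(2, 1)  # 2/3
#' @export
uniform_robustness_mesa <- function(L, k, approx = FALSE) {
  L <- .check_L_any(L)
  if (k < 0 || k > L) stop("'k' must be in 0..L", call. = FALSE)
  if (approx) return(min(2 * k / L, 1))
  sizes <- choose(L, 0:k)
  (sizes[k + 1] * k / L + sum(sizes[-(k + 1)])) / sum(sizes)
}

#' Expected robustness of a uniform population on percolation landscapes
#'
#' Ensemble average of the robustness of a uniform distribution over the
#' viable set, accounting for the binomial distribution of `|V|` and
#' assigning 0 to empty landscapes:
#' `(2^L * p - 1 + (1 - p)^(2^L)) / (2^L - 1)`.
#' For `2^L * p >> 1` this is approximately `p`.
#'
#' @param L number of loci.
#' @param p viability probability.
#' @return expected robustness.
#' @export
expected_uniform_robustness_percolation <- function(L, p) {
  L <- .check_L(L)
  .check_prob(p, "p")
  n <- 2^L
  (n * p - 1 + (1 - p)^n) / (n - 1)
}

#' Maximum genotype robustness of a landscape
#'
#' Maximum of `m_sigma` over viable genotypes; an upper bound for the
#' population robustness of any stationary state. Averaging this over an
#' ensemble of random landscapes estimates the expected maximal robustness.
#'
#' @param land a [fitness_landscape()].
#' @return robustness in `[0, 1]`.
#' @export
max_robustness <- function(land) {
  .check_landscape(land)
  viable <- land$w > 0
  if (!any(viable)) stop("landscape has no viable genotype", call. = FALSE)
  max(genotype_robustness(land)[viable])
}

#' Connected components of the viable network
#'
#' Builds the neutral network graph (viable genotypes joined when at Hamming
#' distance 1) and returns its connected components.
#'
#' @param land a neutral [fitness_landscape()].
#' @return list with `membership` (component id per viable genotype, named by
#'   index), `sizes` (component sizes, sorted decreasing) and `n_components`.
#' @export
viable_components <- function(land) {
  .check_landscape(land)
  L <- land$L
  viable_idx <- which(land$w > 0) - 1L
  if (length(viable_idx) == 0)
    return(list(membership = integer(0), sizes = integer(0), n_components = 0L))
  vset <- logical(2^L)
  vset[viable_idx + 1L] <- TRUE
  # undirected hypercube edges among viable genotypes, each listed once
  from <- integer(0); to <- integer(0)
  for (i in 0:(L - 1L)) {
    nb <- bitwXor(viable_idx, 2L^i)
    keep <- vset[nb + 1L] & nb > viable_idx
    from <- c(from, viable_idx[keep]); to <- c(to, nb[keep])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(viable_idx)))
  comp <- igraph::components(g)
  membership <- comp$membership
  names(membership) <- igraph::V(g)$name
  list(membership = membership,
       sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       n_components = comp$no)
}
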