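# Genotype-space primitives on the binary hypercube {0,1}^L.
#
# Genotypes are encoded as 0-based integer indices in [0, 2^L): bit i of the
# index stores the allele at locus i (bit 0 = first locus, set bit = allele 1).
# Frequency vectors are plain numeric vectors of length 2^L; element i + 1
# holds the frequency of genotype index i.

# per-process cache of index tables keyed by L (flip permutations, popcounts,
# Walsh-Hadamard butterflies, crossover pair tables)
.nn_cache <- new.env(parent = emptyenv())

.cache_key <- function(prefix, L) paste0(prefix, ".", L)

.check_L_any <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1 || L != floor(L))
    stop("'L' must be a single positive integer", call. = FALSE)
  as.integer(L)
}

.check_L <- function(L) {
  L <- .check_L_any(L)
  if (L > 25) stop("'L' larger than 25 is not supported for full genotype spaces",
                   call. = FALSE)
  L
}

.check_genotype <- function(g, L) {
  if (any(g < 0) || any(g >= 2^L) || any(g != floor(g)))
    stop("genotype index out of range [0, 2^L)", call. = FALSE)
  as.integer(g)
}

#' Number of set bits of an integer vector
#'
#' @param x vector of non-negative integers.
#' @return integer vector of the same length with the binary popcount of each
#'   element.
#' @keywords internal
bit_count <- function(x) {
  x <- as.integer(x)
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + x %% 2L
    x <- x %/% 2L
  }
  n
}

# popcount of 0:(2^L - 1), cached
.popcounts <- function(L) {
  key <- .cache_key("pop", L)
  if (is.null(.nn_cache[[key]]))
    .nn_cache[[key]] <- bit_count(0:(2^L - 1L))
  .nn_cache[[key]]
}

#' Convert between genotype indices and allele vectors
#'
#' `genotype_bits()` expands an index into its length-`L` allele vector
#' (locus 1 first); `genotype_index()` is the inverse.
#'
#' @param index genotype index in `[0, 2^L)`.
#' @param L number of loci.
#' @param bits 0/1 vector of alleles, first locus first.
#' @return `genotype_bits()` an integer 0/1 vector of length `L`;
#'   `genotype_index()` a single integer index.
#' @examples
#' genotype_bits(5, L = 3)        # c(1, 0, 1)
#' genotype_index(c(1, 0, 1))     # 5
#' @export
genotype_bits <- function(index, L) {
  L <- .check_L(L)
  index <- .check_genotype(index, L)
  vapply(0:(L - 1L), function(i) bitwAnd(bitwShiftR(index, i), 1L), integer(1))
}

#' @rdname genotype_bits
#' @export
genotype_index <- function(bits) {
  if (!all(bits %in% c(0, 1))) stop("alleles must be 0 or 1", call. = FALSE)
  as.integer(sum(as.integer(bits) * 2^(seq_along(bits) - 1L)))
}

#' Hamming distance between genotypes
#'
#' Counts the loci at which two genotypes differ, i.e. the number of point
#' mutations separating them on the hypercube.
#'
#' @param a,b genotype indices (vectors are recycled element-wise).
#' @param L number of loci (used for validation only).
#' @return non-negative integer vector of distances.
#' @examples
#' hamming_distance(genotype_index(c(0, 1, 1)), genotype_index(c(1, 1, 0)), L = 3)
#' @export
hamming_distance <- function(a, b, L) {
  L <- .check_L(L)
  a <- .check_genotype(a, L)
  b <- .check_genotype(b, L)
  bit_count(bitwXor(a, b))
}

#' Point-mutation neighbours of a genotype
#'
#' @param a a single genotype index.
#' @param L number of loci.
#' @return integer vector of the `L` genotypes at Hamming distance 1, ordered
#'   by ascending flipped-locus index.
#' @export
neighbors <- function(a, L) {
  L <- .check_L(L)
  a <- .check_genotype(a, L)
  bitwXor(a, 2L^(0:(L - 1L)))
}

#' Antipodal genotype
#'
#' Returns the genotype with every allele flipped, the unique genotype at
#' maximal Hamming distance `L`.
#'
#' @inheritParams neighbors
#' @return integer genotype index.
#' @export
antipodal <- function(a, L) {
  L <- .check_L(L)
  a <- .check_genotype(a, L)
  bitwXor(a, 2L^L - 1L)
}

#' Dense symmetric mutation matrix
#'
#' Builds the `2^L x 2^L` matrix with entries
#' `U[s, k] = (1 - mu)^(L - d(s, k)) * mu^d(s, k)`, the probability that
#' genotype `k` mutates to genotype `s` in one generation under independent
#' per-locus symmetric mutation at rate `mu`. The matrix is doubly stochastic.
#' Dense construction is restricted to `L <= 12`; beyond that use the
#' factorized [apply_mutation()].
#'
#' @param L number of loci.
#' @param mu per-locus mutation probability in `[0, 1]`.
#' @return a `2^L x 2^L` numeric matrix.
#' @export
mutation_matrix <- function(L, mu) {
  L <- .check_L(L)
  .check_prob(mu, "mu")
  if (L > 12) stop("dense mutation matrix restricted to L <= 12; use apply_mutation()",
                   call. = FALSE)
  idx <- 0:(2^L - 1L)
  d <- outer(idx, idx, function(a, b) bit_count(bitwXor(a, b)))
  matrix((1 - mu)^(L - d) * mu^d, nrow = 2^L)
}

.check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  p
}

.check_freq <- function(p, L, tol = 1e-6) {
  if (length(p) != 2^L) stop("frequency vector has wrong length for L", call. = FALSE)
  if (any(p < 0)) stop("frequency vector has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > tol) stop("frequency vector does not sum to 1", call. = FALSE)
  invisible(p)
}

# flip permutation table: column i holds the 1-based positions of genotypes
# with locus i flipped
.flip_table <- function(L) {
  key <- .cache_key("flip", L)
  if (is.null(.nn_cache[[key]])) {
    idx <- 0:(2^L - 1L)
    .nn_cache[[key]] <- vapply(0:(L - 1L),
                               function(i) bitwXor(idx, 2L^i) + 1L,
                               integer(2^L))
  }
  .nn_cache[[key]]
}

#' Apply one round of symmetric mutation to a frequency vector
#'
#' Computes `U %*% p` for the mutation matrix of [mutation_matrix()] without
#' materializing it: mutation acts independently per locus, so the dense
#' matrix factorizes into `L` rank-2 updates
#' `p <- (1 - mu) * p + mu * p[locus flipped]`.
#'
#' @param p frequency vector over all `2^L` genotypes.
#' @param mu per-locus mutation probability.
#' @param L number of loci; defaults to `log2(length(p))`.
#' @param method `"factorized"` (default, any `L`) or `"dense"`
#'   (`L <= 12`, used for cross-checks).
#' @return mutated frequency vector (sums to 1).
#' @examples
#' apply_mutation(c(1, 0, 0, 0), mu = 0.1)  # c(0.81, 0.09, 0.09, 0.01)
#' @export
apply_mutation <- function(p, mu, L = as.integer(round(log2(length(p)))),
                           method = c("factorized", "dense")) {
  method <- match.arg(method)
  L <- .check_L(L)
  .check_prob(mu, "mu")
  .check_freq(p, L)
  if (method == "dense") return(as.vector(mutation_matrix(L, mu) %*% p))
  flips <- .flip_table(L)
  for (i in seq_len(L)) p <- (1 - mu) * p + mu * p[flips[, i]]
  p
}

# renormalization guard used after composite generation steps
.renorm <- function(p, warn_tol = 1e-9) {
  s <- sum(p)
  if (abs(s - 1) > warn_tol)
    warning(sprintf("frequency vector drifted from 1 by %.3g before renormalization",
                    s - 1), call. = FALSE)
  p / s
}
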