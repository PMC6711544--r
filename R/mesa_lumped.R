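# Exact Hamming-class (lumped) dynamics for permutation-symmetric mesa
# landscapes, plus closed-form approximations for the stationary robustness
# with and without recombination.
#
# For a landscape that depends on genotypes only through the number of
# mutant alleles d, the dynamics without recombination (and with communal
# recombination) closes on the L + 1 class frequencies f_0..f_L, which makes
# genome lengths of order 10^3 tractable.

#' Lump genotype frequencies into Hamming classes
#'
#' `lump_frequencies()` sums the frequencies of all `choose(L, d)` genotypes
#' at distance `d` from the wild type; `expand_lumped()` is the
#' equidistributing right inverse.
#'
#' @param f frequency vector over `2^L` genotypes.
#' @param fd class frequency vector of length `L + 1`.
#' @param L number of loci.
#' @return a vector over classes `0..L`, or over genotypes respectively.
#' @export
lump_frequencies <- function(f, L = as.integer(round(log2(length(f))))) {
  L <- .check_L(L)
  d <- .popcounts(L)
  as.vector(rowsum(f, d, reorder = TRUE))
}

#' @rdname lump_frequencies
#' @export
expand_lumped <- function(fd, L = length(fd) - 1L) {
  L <- .check_L(L)
  if (length(fd) != L + 1) stop("'fd' must have length L + 1", call. = FALSE)
  d <- .popcounts(L)
  fd[d + 1L] / choose(L, d)
}

#' Hamming-class mutation kernel
#'
#' Transition matrix `K[d + 1, d' + 1] = P(d -> d')` of the class process
#' induced by independent symmetric per-locus mutation. In `"exact"` mode
#' the probability sums over all combinations of `j` back mutations (among
#' the `d` mutant loci) and `i` forward mutations (among the `L - d`
#' wild-type loci) with `d' = d - j + i`. In `"single_flip"` mode at most
#' one point mutation per generation is assumed (valid for `L * mu << 1`):
#' `P(d -> d+1) = (L-d) mu`, `P(d -> d-1) = d mu`, `P(d -> d) = 1 - L mu`.
#'
#' @param L number of loci.
#' @param mu per-locus mutation rate (`L * mu < 1` required for
#'   single-flip).
#' @param mode `"exact"` or `"single_flip"`.
#' @return an `(L+1) x (L+1)` row-stochastic matrix.
#' @export
lumped_mutation_kernel <- function(L, mu, mode = c("exact", "single_flip")) {
  mode <- match.arg(mode)
  L <- .check_L_any(L)
  .check_prob(mu, "mu")
  n <- L + 1L
  K <- matrix(0, n, n)
  if (mode == "single_flip") {
    if (L * mu >= 1)
      stop("single-flip kernel requires L * mu < 1", call. = FALSE)
    for (d in 0:L) {
      if (d < L) K[d + 1L, d + 2L] <- (L - d) * mu
      if (d > 0) K[d + 1L, d] <- d * mu
      K[d + 1L, d + 1L] <- 1 - L * mu
    }
  } else {
    for (d in 0:L) {
      back <- stats::dbinom(0:d, d, mu)          # j reversions among d mutants
      fwd <- stats::dbinom(0:(L - d), L - d, mu) # i new mutations
      dist <- numeric(n)
      for (j in 0:d) {
        targets <- (d - j) + 0:(L - d)           # d' = d - j + i
        dist[targets + 1L] <- dist[targets + 1L] + back[j + 1L] * fwd
      }
      K[d + 1L, ] <- dist
    }
  }
  K
}

.mesa_class_robustness <- function(L, k) {
  m <- numeric(L + 1L)
  if (k > 0) m[1:k] <- 1
  m[k + 1L] <- k / L
  m
}

#' Stationary lumped mesa dynamics without recombination
#'
#' Selection on the mesa landscape truncates the classes `d > k` and
#' renormalizes (exact for two-level fitness); mutation acts through the
#' class kernel of [lumped_mutation_kernel()]. The stationary post-selection
#' state is the Perron eigenvector of the restricted
#' selection-then-mutation operator on classes `0..k`, computed by dense
#' eigendecomposition (the power-iteration limit of the map). Robustness is
#' reported both after selection (`M_nr`) and after mutation (`m_nr`), using
#' the class robustness 1 for `d < k`, `k/L` at `d = k` and 0 beyond; the
#' two are linked by `m_nr = M_nr (1 - U) + M_nr^2 U` in the single-flip
#' regime, and that consistency value is returned alongside.
#'
#' @param L number of loci.
#' @param k mesa width.
#' @param U genome-wide mutation rate `U = L * mu`.
#' @param mode mutation kernel mode, see [lumped_mutation_kernel()].
#' @return list with `M_nr`, `m_nr`, `m_nr_eq31` (the consistency value),
#'   `q` (post-selection class frequencies, length `L + 1`), `p`
#'   (post-mutation class frequencies), `residual` and `converged`.
#' @examples
#' stationary_lumped_nr(100, 10, 0.01, mode = "single_flip")$m_nr
#' @export
stationary_lumped_nr <- function(L, k, U, mode = c("exact", "single_flip")) {
  mode <- match.arg(mode)
  L <- .check_L_any(L)
  if (k < 0 || k > L) stop("'k' must be in 0..L", call. = FALSE)
  mu <- U / L
  K <- lumped_mutation_kernel(L, mu, mode)
  # The class chain is reversible with respect to the binomial(1/2) measure
  # pi_d = C(L, d) 2^-L, so the restricted selection-then-mutation operator
  # B[d', d] = K[d -> d'] (classes 0..k) is diagonally similar to the
  # symmetric matrix S[d', d] = sqrt(K[d -> d'] K[d' -> d]). The symmetric
  # eigenproblem is numerically stable even at L ~ 10^3, where B itself is
  # severely non-normal; the Perron vector is recovered as
  # q_d = sqrt(C(L, d)) u_d (evaluated in log scale).
  Kr <- K[1:(k + 1L), 1:(k + 1L), drop = FALSE]
  S <- sqrt(Kr * t(Kr))
  ev <- eigen(S, symmetric = TRUE)
  u <- ev$vectors[, which.max(ev$values)]
  logw <- 0.5 * lchoose(L, 0:k)
  v <- u * exp(logw - max(logw))
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8 * max(abs(v))))
    warning("leading eigenvector has negative components; result may be unreliable")
  v <- pmax(v, 0)
  q <- numeric(L + 1L)
  q[1:(k + 1L)] <- v / sum(v)
  p <- as.vector(q %*% K)
  # fixed-point residual of the selection + mutation map
  q_next <- numeric(L + 1L)
  q_next[1:(k + 1L)] <- p[1:(k + 1L)] / sum(p[1:(k + 1L)])
  res <- max(abs(q_next - q))
  mclass <- .mesa_class_robustness(L, k)
  M_nr <- sum(mclass * q)
  m_nr <- sum(mclass * p)
  list(M_nr = M_nr, m_nr = m_nr,
       m_nr_eq31 = M_nr * (1 - U) + M_nr^2 * U,
       q = q, p = p, residual = res, converged = res < 1e-12)
}

#' Stationary lumped mesa dynamics with communal recombination
#'
#' Iterates selection (truncation of classes `d > k`), class mutation, and
#' the communal projection: the class distribution after recombination is
#' `Binomial(L, x)` where `x` is the post-mutation mean mutant-allele
#' frequency `sum(d * p_d) / L`. The projection enforces linkage
#' equilibrium every generation and conserves `x`. Robustness `m_cr` is
#' measured on the stationary state at the generation boundary (after the
#' projection).
#'
#' @inheritParams stationary_lumped_nr
#' @param tol max-norm convergence tolerance on the class distribution.
#' @param max_iter iteration cap.
#' @return list with `m_cr`, `x` (stationary mutant-allele frequency), `f`
#'   (stationary class frequencies), `iterations`, `residual`, `converged`.
#' @examples
#' stationary_lumped_communal(100, 10, 0.01, mode = "single_flip")$m_cr
#' @export
stationary_lumped_communal <- function(L, k, U, mode = c("exact", "single_flip"),
                                       tol = 1e-14, max_iter = 1e6) {
  mode <- match.arg(mode)
  L <- .check_L_any(L)
  if (k < 0 || k > L) stop("'k' must be in 0..L", call. = FALSE)
  mu <- U / L
  K <- lumped_mutation_kernel(L, mu, mode)
  d_all <- 0:L
  f <- stats::dbinom(d_all, L, min(k / L, 0.5) / 2)  # any interior start
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    q <- f
    q[d_all > k] <- 0
    s <- sum(q)
    if (s <= 0) stop("extinction: selection removed all class mass", call. = FALSE)
    q <- q / s
    p <- as.vector(q %*% K)
    x <- sum(d_all * p) / L
    f_new <- stats::dbinom(d_all, L, x)
    res <- max(abs(f_new - f))
    f <- f_new
    if (res < tol) break
  }
  mclass <- .mesa_class_robustness(L, k)
  list(m_cr = sum(mclass * f), x = sum(d_all * f) / L, f = f,
       iterations = it, residual = res, converged = res < tol)
}

#' Closed-form approximations for the communal-recombination robustness
#'
#' Small-mutation-rate expansion of the stationary robustness under communal
#' recombination on the mesa landscape:
#' finite-`L` form `1 - C(L-1, k)^(1/(k+1)) mu^(k/(k+1)) + k/(k+1) mu` and
#' the `L >> k` form `1 - U^(k/(k+1)) (k!)^(-1/(k+1)) + k/(k+1) mu` with
#' `U = L mu`. The deficit `1 - m_cr` scales as `U^(k/(k+1))`.
#'
#' @param L number of loci.
#' @param k mesa width.
#' @param mu per-locus mutation rate (small; a warning is issued when the
#'   leading correction exceeds 0.5).
#' @return list with `finite_L` and `large_L` evaluations.
#' @export
approx_mcr <- function(L, k, mu) {
  L <- .check_L_any(L)
  if (k < 1 || k > L) stop("'k' must be in 1..L", call. = FALSE)
  .check_prob(mu, "mu")
  U <- L * mu
  corr_f <- exp(lchoose(L - 1, k) / (k + 1)) * mu^(k / (k + 1))
  corr_l <- U^(k / (k + 1)) * exp(-lgamma(k + 1) / (k + 1))
  if (corr_f > 0.5)
    warning("leading correction exceeds 0.5; expansion outside its regime of validity")
  list(finite_L = 1 - corr_f + k / (k + 1) * mu,
       large_L = 1 - corr_l + k / (k + 1) * mu)
}

#' Scaled largest Hermite zero
#'
#' Returns `y_k = 2 z^2` where `z` is the largest zero of the physicists'
#' Hermite polynomial `H_{k+1}`; equivalently `sqrt(y_k / 2)` is that
#' largest zero. The zeros are computed as eigenvalues of the symmetric
#' Jacobi matrix of the Gauss-Hermite rule (Golub-Welsch), so arbitrary `k`
#' is handled stably. `y_1 = 1`, `y_2 = 3`, and `y_k ~ 4k` for large `k`.
#'
#' @param k positive integer.
#' @return `y_k > 0`.
#' @export
hermite_yk <- function(k) {
  if (k < 1 || k != floor(k)) stop("'k' must be a positive integer", call. = FALSE)
  n <- k + 1L
  if (n == 1L) return(0)
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  z <- max(eigen(J, symmetric = TRUE, only.values = TRUE)$values)
  2 * z^2
}

#' Closed-form approximations for the non-recombining robustness
#'
#' Hermite approximation for `k/L << 1`: `M_nr = sqrt(y_k / L)` with `y_k`
#' from [hermite_yk()], and `m_nr = M_nr (1 - U) + M_nr^2 U`. Joint-limit
#' form for `k, L -> infinity` at fixed `x = k/L`:
#' `M_nr = 2 sqrt(x (1 - x))` for `x < 1/2` and `M_nr = 1` (hence
#' `m_nr = 1`) for `x >= 1/2`.
#'
#' @param L number of loci.
#' @param k mesa width (`>= 1`).
#' @param U genome-wide mutation rate `L * mu`.
#' @return list with `M_hermite`, `m_hermite`, `M_joint`, `m_joint`.
#' @export
approx_mnr <- function(L, k, U) {
  L <- .check_L_any(L)
  if (k < 1 || k > L) stop("'k' must be in 1..L", call. = FALSE)
  Mh <- sqrt(hermite_yk(k) / L)
  x <- k / L
  Mj <- if (x < 0.5) 2 * sqrt(x * (1 - x)) else 1
  list(M_hermite = Mh, m_hermite = Mh * (1 - U) + Mh^2 * U,
       M_joint = Mj,
       m_joint = if (x >= 0.5) 1 else Mj * (1 - U) + Mj^2 * U)
}
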