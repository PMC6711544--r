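# Recombination schemes, tensors, the recombination step and the
# recombination weight.
#
# The uniform-crossover step at full strength is evaluated in Walsh-Hadamard
# coordinates: writing phat(S) = sum_sigma (-1)^|S & sigma| p_sigma, the
# offspring transform obeys
#   fhat(S) = 2^-|S| * sum_{A subset of S} phat(A) * phat(S \ A),
# a subset convolution with 3^L terms in total. The one-point step reduces to
# averages of outer products of prefix/suffix marginals. Both avoid the 8^L
# tensor; the materialized tensor is kept for small L as the reference
# object.

#' Recombination scheme descriptor
#'
#' @param kind one of `"uniform"`, `"one_point"`, `"communal"`.
#' @param r recombination rate in `[0, 1]`: the probability that an offspring
#'   is produced by crossover rather than clonally.
#' @return an object of class `recombination_scheme`.
#' @export
recombination_scheme <- function(kind = c("uniform", "one_point", "communal"),
                                 r = 1) {
  kind <- match.arg(kind)
  .check_prob(r, "r")
  structure(list(kind = kind, r = r), class = "recombination_scheme")
}

#' @export
print.recombination_scheme <- function(x, ...) {
  cat(sprintf("Recombination scheme: %s, r = %g\n", x$kind, x$r))
  invisible(x)
}

.check_scheme <- function(scheme) {
  if (!inherits(scheme, "recombination_scheme"))
    stop("expected a 'recombination_scheme' object", call. = FALSE)
  scheme
}

#' Materialized recombination tensors
#'
#' Builds the full array `R[s, k, t]` of offspring probabilities
#' for each ordered parent pair `(k, t)` (all indices 1-based over genotypes
#' 0..2^L-1). Uniform crossover:
#' `R = r/2^L * prod_i(d(s_i,k_i) + d(s_i,t_i)) + (1-r)/2 * (d_sk + d_st)`
#' with `d` the Kronecker delta. One-point crossover picks one of the `L - 1`
#' cut positions uniformly and joins a prefix of one parent to the suffix of
#' the other (both parent orders). Materialization is restricted to
#' `L <= 8`; the dynamics never needs the tensor.
#'
#' @param L number of loci (`>= 2` for one-point).
#' @param r recombination rate.
#' @return a `2^L x 2^L x 2^L` array; `[offspring, parent1, parent2]`.
#' @export
tensor_uniform <- function(L, r) {
  L <- .check_L(L)
  .check_prob(r, "r")
  if (L > 8) stop("materialized tensors restricted to L <= 8", call. = FALSE)
  n <- 2^L
  idx <- 0:(n - 1L)
  R <- array(0, dim = c(n, n, n))
  for (k in idx) for (t in idx) {
    # loci where parents agree must match the offspring; disagreeing loci free
    agree_mask <- bitwAnd(bitwNot(bitwXor(k, t)), n - 1L)
    d <- bit_count(bitwXor(k, t))
    ok <- bitwAnd(idx, agree_mask) == bitwAnd(k, agree_mask)
    cross <- ifelse(ok, 2^(-d), 0)
    R[, k + 1L, t + 1L] <- r * cross +
      (1 - r) / 2 * ((idx == k) + (idx == t))
  }
  R
}

#' @rdname tensor_uniform
#' @export
tensor_onepoint <- function(L, r) {
  L <- .check_L(L)
  if (L < 2) stop("one-point crossover requires L >= 2", call. = FALSE)
  .check_prob(r, "r")
  if (L > 8) stop("materialized tensors restricted to L <= 8", call. = FALSE)
  n <- 2^L
  idx <- 0:(n - 1L)
  R <- array(0, dim = c(n, n, n))
  w <- r / (2 * (L - 1))
  for (k in idx) for (t in idx) {
    acc <- numeric(n)
    for (cut in 1:(L - 1)) {
      low <- 2L^cut - 1L          # loci 1..cut
      high <- n - 1L - low        # loci cut+1..L
      s1 <- bitwOr(bitwAnd(k, low), bitwAnd(t, high))
      s2 <- bitwOr(bitwAnd(t, low), bitwAnd(k, high))
      acc[s1 + 1L] <- acc[s1 + 1L] + w
      acc[s2 + 1L] <- acc[s2 + 1L] + w
    }
    acc[k + 1L] <- acc[k + 1L] + (1 - r) / 2
    acc[t + 1L] <- acc[t + 1L] + (1 - r) / 2
    R[, k + 1L, t + 1L] <- acc
  }
  R
}

# ---- fast Walsh-Hadamard machinery ----------------------------------------

# butterfly index pairs per pass, cached
.wht_plan <- function(L) {
  key <- .cache_key("wht", L)
  if (is.null(.nn_cache[[key]])) {
    n <- 2^L
    idx <- 0:(n - 1L)
    plan <- lapply(0:(L - 1L), function(b) {
      i0 <- idx[bitwAnd(idx, 2L^b) == 0L]
      list(i0 = i0 + 1L, i1 = bitwXor(i0, 2L^b) + 1L)
    })
    .nn_cache[[key]] <- plan
  }
  .nn_cache[[key]]
}

# unnormalized Walsh-Hadamard transform; self-inverse up to factor 2^L
.wht <- function(x, L) {
  plan <- .wht_plan(L)
  for (pq in plan) {
    a <- x[pq$i0]; b <- x[pq$i1]
    x[pq$i0] <- a + b
    x[pq$i1] <- a - b
  }
  x
}

# subset-convolution table: for every S, all ordered pairs (A, S\A);
# stored as flat index vectors plus the group key S and scale 2^-|S|
.uniform_pairs <- function(L) {
  key <- .cache_key("upairs", L)
  if (is.null(.nn_cache[[key]])) {
    Ssz <- 3L^L
    Aidx <- integer(Ssz); Bidx <- integer(Ssz); Sgrp <- integer(Ssz)
    pos <- 0L
    for (S in 0:(2L^L - 1L)) {
      sub <- S
      repeat {
        pos <- pos + 1L
        Aidx[pos] <- sub
        Bidx[pos] <- bitwXor(S, sub)  # S \ sub
        Sgrp[pos] <- S
        if (sub == 0L) break
        sub <- bitwAnd(sub - 1L, S)
      }
    }
    scale <- 2^(-bit_count(0:(2L^L - 1L)))
    .nn_cache[[key]] <- list(A = Aidx + 1L, B = Bidx + 1L, S = Sgrp,
                             scale = scale)
  }
  .nn_cache[[key]]
}

# bilinear r = 1 uniform-crossover map applied to an arbitrary vector:
# T(v)_sigma = sum_{k,t} v_k v_t prod_i (delta_ski + delta_sti)/2
.uniform_map1 <- function(v, L) {
  vh <- .wht(v, L)
  tab <- .uniform_pairs(L)
  prod <- vh[tab$A] * vh[tab$B]
  conv <- unname(rowsum(prod, tab$S, reorder = FALSE)[, 1L]) * tab$scale
  .wht(conv, L) / 2^L
}

# bilinear r = 1 one-point map: average over cuts of prefix/suffix marginal
# outer products; relies on genotype order having locus 0 as fastest bit
.onepoint_map1 <- function(v, L) {
  n <- 2^L
  acc <- numeric(n)
  for (cut in 1:(L - 1)) {
    m <- matrix(v, nrow = 2^cut)
    acc <- acc + as.vector(rowSums(m) %o% colSums(m))
  }
  acc / (L - 1)
}

# linkage-equilibrium product distribution with the allele frequencies of p
.le_projection <- function(p, L) {
  idx <- 0:(2^L - 1L)
  q <- rep(1, 2^L)
  for (i in seq_len(L)) {
    x <- sum(p[bitwAnd(idx, 2L^(i - 1L)) > 0L])  # allele-1 frequency at locus i
    has1 <- bitwAnd(idx, 2L^(i - 1L)) > 0L
    q <- q * ifelse(has1, x, 1 - x)
  }
  q
}

#' Apply one recombination step to a frequency vector
#'
#' For uniform and one-point crossover the next-generation frequencies are
#' the tensor contraction `f_s = sum_{k,t} R[s|k,t] p_k p_t`, evaluated with
#' fast transforms (no tensor is built). The communal scheme draws each
#' offspring locus from a random member of the whole population: at full
#' strength it replaces `p` by the linkage-equilibrium product distribution
#' of its allele frequencies, and at rate `r < 1` the output is the
#' `r`-mixture of that projection with the unrecombined `p`. All schemes
#' preserve per-locus allele frequencies exactly; `r = 0` is the identity.
#'
#' @param p frequency vector over `2^L` genotypes.
#' @param scheme a [recombination_scheme()].
#' @param L number of loci; defaults to `log2(length(p))`.
#' @return recombined frequency vector.
#' @export
recombination_step <- function(p, scheme, L = as.integer(round(log2(length(p))))) {
  .check_scheme(scheme)
  L <- .check_L(L)
  .check_freq(p, L)
  r <- scheme$r
  if (r == 0) return(p)
  mixed <- switch(scheme$kind,
    uniform = .uniform_map1(p, L),
    one_point = {
      if (L < 2) stop("one-point crossover requires L >= 2", call. = FALSE)
      .onepoint_map1(p, L)
    },
    communal = .le_projection(p, L))
  (1 - r) * p + r * mixed
}

#' Recombination weight of every genotype
#'
#' The recombination weight `lambda_sigma` is the fitness-weighted chance for
#' genotype `sigma` to arise as a recombinant:
#' `lambda_s = 2^-L sum_{k,t} R[s|k,t] w_k w_t`.
#' On neutral landscapes this counts the ordered pairs of viable parents able
#' to produce `sigma`, normalized so that `lambda = 1` everywhere when all
#' genotypes are viable; the weights always sum to `(sum w)^2 / 2^L`
#' (`|V|^2 / 2^L` for neutral landscapes). At `r = 0` the weight is
#' proportional to the genotype's own fitness, `lambda = wbar_u * w` with
#' `wbar_u = 2^-L sum w`; for general `r` it interpolates linearly between
#' the `r = 0` and `r = 1` weights. The weight is not defined for the
#' communal scheme, which has no parent-pair tensor.
#'
#' @param land a [fitness_landscape()].
#' @param scheme a [recombination_scheme()] of kind uniform or one-point.
#' @return numeric vector `lambda` over all genotypes.
#' @export
recombination_weight <- function(land, scheme) {
  .check_landscape(land)
  .check_scheme(scheme)
  if (scheme$kind == "communal")
    stop("recombination weight is not defined for the communal scheme",
         call. = FALSE)
  L <- land$L
  w <- land$w
  r <- scheme$r
  lam0 <- w * sum(w) / 2^L
  if (r == 0) return(lam0)
  map1 <- if (scheme$kind == "uniform") .uniform_map1(w, L) else {
    if (L < 2) stop("one-point crossover requires L >= 2", call. = FALSE)
    .onepoint_map1(w, L)
  }
  lam1 <- map1 / 2^L
  (1 - r) * lam0 + r * lam1
}

#' Recombination center
#'
#' The genotype maximizing the recombination weight; ties are broken by the
#' lowest genotype index.
#'
#' @param lambda weight vector as returned by [recombination_weight()].
#' @return integer genotype index of the center.
#' @export
recombination_center <- function(lambda) {
  if (all(lambda <= 0)) stop("all recombination weights are zero", call. = FALSE)
  unname(which.max(lambda)) - 1L
}
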