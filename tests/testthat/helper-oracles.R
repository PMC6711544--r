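# Brute-force oracles kept independent of the fast implementation paths.

# direct contraction f_s = sum_{k,t} R[s,k,t] p_k p_t
contract_tensor <- function(R, p) {
  n <- length(p)
  vapply(seq_len(n), function(s) sum(R[s, , ] * (p %o% p)), numeric(1))
}

# per-locus allele-1 frequencies of a genotype frequency vector
allele_freqs <- function(f, L) {
  idx <- 0:(2^L - 1L)
  vapply(0:(L - 1L), function(i) sum(f[bitwAnd(idx, 2L^i) > 0L]), numeric(1))
}

# Hamming class of every genotype index
class_of <- function(L) {
  vapply(0:(2^L - 1L), function(i) sum(genotype_bits(i, L)), integer(1))
}

# lump the dense mutation matrix into a class kernel (uses one column per
# class; valid by permutation symmetry)
brute_lumped_kernel <- function(L, mu) {
  U <- mutation_matrix(L, mu)
  d <- class_of(L)
  K <- matrix(0, L + 1, L + 1)
  for (dd in 0:L) {
    src <- which(d == dd)[1]
    K[dd + 1, ] <- vapply(0:L, function(dp) sum(U[d == dp, src]), numeric(1))
  }
  K
}

random_simplex <- function(n) {
  p <- stats::runif(n)
  p / sum(p)
}
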