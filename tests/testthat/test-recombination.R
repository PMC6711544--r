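test_that("recombination tensors are normalized, parent-symmetric and supported
           on parental alleles", {
  set.seed(3)
  for (builder in list(tensor_uniform, tensor_onepoint)) {
    R <- builder(3, 0.7)
    for (trial in 1:15) {
      k <- sample(0:7, 1); t <- sample(0:7, 1)
      expect_equal(sum(R[, k + 1, t + 1]), 1, tolerance = 1e-14)
      expect_equal(R[, k + 1, t + 1], R[, t + 1, k + 1])
      # offspring must agree with a parent at every locus
      agree <- bitwAnd(bitwNot(bitwXor(k, t)), 7L)
      ok <- bitwAnd(0:7, agree) == bitwAnd(k, agree)
      expect_true(all(R[!ok, k + 1, t + 1] == 0))
    }
  }
})

test_that("crossover of canonical parent pairs gives the textbook offspring laws", {
  # identical parents: clonal regardless of r
  R <- tensor_uniform(2, 0.8)
  expect_equal(R[, 2, 2], c(0, 1, 0, 0))
  # antipodal parents, uniform r = 1: offspring uniform on the hypercube
  R1 <- tensor_uniform(2, 1)
  expect_equal(R1[, 1, 4], rep(0.25, 4))
  # antipodal parents, one-point r = 1, L = 2: single cut, both orders
  O1 <- tensor_onepoint(2, 1)
  expect_equal(O1[, 1, 4], c(0, 0.5, 0.5, 0))
  # r = 0: clonal mixture of the two parents
  O0 <- tensor_onepoint(3, 0)
  expect_equal(O0[, 2, 5], 0.5 * ((0:7 == 1) + (0:7 == 4)))
})

test_that("fast recombination step equals brute-force tensor contraction", {
  set.seed(5)
  for (L in c(2, 3, 4)) {
    p <- random_simplex(2^L)
    for (r in c(0.3, 1)) {
      expect_equal(recombination_step(p, recombination_scheme("uniform", r)),
                   contract_tensor(tensor_uniform(L, r), p), tolerance = 1e-13)
      expect_equal(recombination_step(p, recombination_scheme("one_point", r)),
                   contract_tensor(tensor_onepoint(L, r), p), tolerance = 1e-13)
    }
  }
})

test_that("recombination preserves allele frequencies and the simplex; r = 0 is
           the identity", {
  set.seed(9)
  L <- 4
  for (kind in c("uniform", "one_point", "communal")) {
    p <- random_simplex(2^L)
    expect_equal(recombination_step(p, recombination_scheme(kind, 0)), p)
    for (r in c(0.25, 1)) {
      out <- recombination_step(p, recombination_scheme(kind, r))
      expect_equal(sum(out), 1, tolerance = 1e-12)
      expect_true(all(out >= -1e-15))
      expect_equal(allele_freqs(out, L), allele_freqs(p, L), tolerance = 1e-12)
    }
  }
})

test_that("full-strength crossover restores linkage equilibrium at two loci", {
  set.seed(13)
  p <- random_simplex(4)
  for (kind in c("one_point", "communal")) {
    f <- recombination_step(p, recombination_scheme(kind, 1))
    expect_equal(f[1] * f[4], f[2] * f[3], tolerance = 1e-13)
  }
  # communal at r = 1 is exactly the product measure of the allele frequencies
  f <- recombination_step(p, recombination_scheme("communal", 1))
  x <- allele_freqs(p, 2)
  expect_equal(f, c((1 - x[1]) * (1 - x[2]), x[1] * (1 - x[2]),
                    (1 - x[1]) * x[2], x[1] * x[2]), tolerance = 1e-14)
})

test_that("recombination weight reduces to fitness at r = 0 and is linear in r", {
  land <- make_percolation(5, 0.5, seed = 21)
  wtilde <- sum(land$w) / 2^5
  expect_equal(recombination_weight(land, recombination_scheme("uniform", 0)),
               wtilde * land$w)
  lam0 <- recombination_weight(land, recombination_scheme("uniform", 0))
  lam1 <- recombination_weight(land, recombination_scheme("uniform", 1))
  lam_mid <- recombination_weight(land, recombination_scheme("uniform", 0.3))
  expect_equal(lam_mid, 0.7 * lam0 + 0.3 * lam1, tolerance = 1e-13)
  for (r in c(0, 0.3, 1)) {
    lam <- recombination_weight(land, recombination_scheme("one_point", r))
    expect_equal(sum(lam), sum(land$w)^2 / 2^5, tolerance = 1e-12)
    expect_true(all(lam >= 0 & lam <= 1 + 1e-12))
  }
  expect_equal(recombination_weight(make_percolation(3, 1, seed = 1),
                                    recombination_scheme("uniform", 1)),
               rep(1, 8), tolerance = 1e-13)
  expect_error(recombination_weight(land, recombination_scheme("communal", 1)),
               "communal")
})

test_that("two-locus weights agree with the closed forms under the rho mapping", {
  land <- make_mesa(2, 1)
  for (r in c(0, 0.4, 1)) {
    expect_equal(recombination_weight(land, recombination_scheme("one_point", r)),
                 unname(weights_twolocus(r)), tolerance = 1e-14)
    expect_equal(recombination_weight(land, recombination_scheme("uniform", r)),
                 unname(weights_twolocus(r / 2)), tolerance = 1e-14)
  }
})

test_that("the mesa recombination center is the wild type and the weight
           vanishes beyond twice the mesa width", {
  land <- make_mesa(10, 2)
  lam <- recombination_weight(land, recombination_scheme("uniform", 1))
  d <- class_of(10)
  expect_equal(recombination_center(lam), 0L)
  expect_true(all(lam[d > 4] == 0))  # recombinants carry at most 2k mutations
  # weight decays with distance (class averages)
  prof <- vapply(0:4, function(dd) mean(lam[d == dd]), numeric(1))
  expect_true(all(diff(prof) < 0))
  # flat landscape: tie broken at the lowest index
  flat <- recombination_weight(make_mesa(3, 3), recombination_scheme("uniform", 1))
  expect_equal(recombination_center(flat), 0L)
  expect_error(recombination_center(rep(0, 8)), "zero")
})
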