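test_that("class mutation kernels are stochastic and the exact kernel equals
           brute-force lumping of the genotype matrix", {
  for (mode in c("exact", "single_flip")) {
    K <- lumped_mutation_kernel(6, 0.01, mode)
    expect_equal(rowSums(K), rep(1, 7), tolerance = 1e-14)
    expect_true(all(K >= 0))
  }
  expect_equal(lumped_mutation_kernel(4, 0.13, "exact"),
               brute_lumped_kernel(4, 0.13), tolerance = 1e-13)
  Ksf <- lumped_mutation_kernel(8, 0.005, "single_flip")
  expect_equal(Ksf[1, 2], 8 * 0.005)   # up-step from the wild-type class is U
  expect_equal(Ksf[3, 2], 2 * 0.005)
  expect_error(lumped_mutation_kernel(8, 0.2, "single_flip"), "single-flip")
})

test_that("lumping and equidistributed expansion are mutually inverse", {
  set.seed(6)
  f <- random_simplex(2^5)
  fd <- lump_frequencies(f)
  expect_length(fd, 6)
  expect_equal(sum(fd), 1)
  expect_equal(lump_frequencies(expand_lumped(fd, 5)), fd, tolerance = 1e-14)
})

test_that("lumped and full-hypercube mesa solvers agree without recombination", {
  for (L in c(4, 6, 8, 10)) {
    k <- 2
    mu <- 0.001
    full <- stationary_state("uniform", make_mesa(L, k), mu,
                             recombination_scheme("uniform", 0))
    lump <- stationary_lumped_nr(L, k, L * mu, "exact")
    expect_lt(abs(full$robustness - lump$m_nr), 1e-8)
    expect_lt(max(abs(lump_frequencies(full$f) - lump$p)), 1e-8)
  }
})

test_that("lumped and full-hypercube mesa solvers agree under communal
           recombination", {
  full <- stationary_state("uniform", make_mesa(6, 2), 0.001,
                           recombination_scheme("communal", 1), tol = 1e-14)
  lump <- stationary_lumped_communal(6, 2, 0.006, "exact")
  expect_lt(abs(full$robustness - lump$m_cr), 1e-10)
  expect_lt(max(abs(lump_frequencies(full$f) - lump$f)), 1e-10)
})

test_that("non-recombining stationary robustness matches its known limits", {
  # two-locus limit: M_nr -> 1/sqrt(2) as U -> 0
  expect_equal(stationary_lumped_nr(2, 1, 1e-8, "single_flip")$M_nr,
               1 / sqrt(2), tolerance = 1e-6)
  # no lethal class at k = L
  expect_equal(stationary_lumped_nr(5, 5, 0.01, "exact")$m_nr, 1)
  # post-selection robustness is independent of U in the single-flip regime
  Ms <- vapply(c(1e-4, 1e-3, 1e-2), function(U)
    stationary_lumped_nr(30, 3, U, "single_flip")$M_nr, numeric(1))
  expect_lt(max(Ms) - min(Ms), 1e-6)
  # the after-selection/after-mutation link holds in the single-flip regime
  res <- stationary_lumped_nr(30, 3, 0.01, "single_flip")
  expect_equal(res$m_nr, res$m_nr_eq31, tolerance = 1e-10)
})

test_that("communal stationary robustness matches its known limits", {
  expect_equal(stationary_lumped_communal(5, 5, 0.01, "exact")$m_cr, 1)
  # at two loci the communal scheme equals the full-crossover closed form
  for (mu in c(1e-4, 0.01)) {
    mcr <- stationary_lumped_communal(2, 1, 2 * mu, "exact")$m_cr
    expect_equal(mcr, (2 + mu - sqrt(mu^2 + 4 * mu)) / 2, tolerance = 1e-10)
  }
  # the projection conserves the mean mutant-allele frequency
  res <- stationary_lumped_communal(20, 4, 0.01, "exact")
  expect_equal(sum((0:20) * res$f) / 20, res$x, tolerance = 1e-12)
  expect_true(res$converged)
})

test_that("the robustness deficit under communal recombination scales as
           U^(k/(k+1))", {
  Us <- 10^seq(-5, -3, by = 0.5)
  for (k in 1:3) {
    ms <- vapply(Us, function(U)
      stationary_lumped_communal(30, k, U, "exact")$m_cr, numeric(1))
    slope <- unname(coef(stats::lm(log(1 - ms) ~ log(Us)))[2])
    expect_lt(abs(slope - k / (k + 1)), 0.05)
  }
})

test_that("closed-form communal approximations match their anchors and track
           the solver", {
  expect_equal(approx_mcr(10, 2, 0)$finite_L, 1)
  mu <- 0.004
  ap <- approx_mcr(2, 1, mu)
  expect_equal(ap$finite_L, 1 - sqrt(mu) + mu / 2, tolerance = 1e-14)
  for (U in c(0.001, 0.01, 0.1)) {
    num <- stationary_lumped_communal(30, 3, U, "exact")$m_cr
    ap <- approx_mcr(30, 3, U / 30)
    expect_lt(abs((1 - ap$finite_L) - (1 - num)), 0.05 * (1 - num) + 1e-5)
  }
})

test_that("scaled Hermite zeros take their closed-form small-k values and
           approach 4k", {
  expect_equal(hermite_yk(1), 1, tolerance = 1e-12)    # H_2 zero at 1/sqrt(2)
  expect_equal(hermite_yk(2), 3, tolerance = 1e-12)    # H_3 zero at sqrt(3/2)
  ys <- vapply(1:10, hermite_yk, numeric(1))
  expect_true(all(diff(ys) > 0))
  expect_gt(hermite_yk(100) / 400, 0.9)
  expect_gt(hermite_yk(100) / 400, hermite_yk(10) / 40)
})

test_that("Hermite and joint-limit approximations bracket the exact
           non-recombining solver in their shared regime", {
  expect_equal(approx_mnr(1000, 500, 0.01)$m_joint, 1)  # x >= 1/2
  expect_equal(approx_mnr(2, 1, 1e-9)$M_hermite, 1 / sqrt(2), tolerance = 1e-12)
  exact <- stationary_lumped_nr(1000, 10, 0.01, "single_flip")$m_nr
  ap <- approx_mnr(1000, 10, 0.01)
  expect_gt(ap$m_hermite, min(exact, ap$m_joint))
  expect_lt(ap$m_hermite, max(exact, ap$m_joint))
  expect_lt(abs(ap$m_hermite - exact), 0.01)
})
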