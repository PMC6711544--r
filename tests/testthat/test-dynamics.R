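test_that("selection reweights by fitness and detects extinction", {
  land <- make_mesa(2, 1)
  flat <- make_mesa(2, 2)
  f <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(selection_step(f, flat), f)
  q <- selection_step(f, land)
  expect_equal(q[4], 0)               # the lethal double mutant is purged
  expect_equal(sum(q), 1)
  expect_equal(q[1] / q[2], f[1] / f[2])
  expect_error(selection_step(c(0, 0, 0, 1), land), "extinction")
})

test_that("a full generation is the identity in the neutral no-force limit and
           fixes the uniform state on an all-viable landscape", {
  flat <- make_mesa(3, 3)
  set.seed(2)
  f <- random_simplex(8)
  expect_equal(generation(f, flat, 0, recombination_scheme("uniform", 0)), f)
  u <- rep(1 / 8, 8)
  for (kind in c("uniform", "one_point", "communal")) {
    out <- generation(u, flat, 0.05, recombination_scheme(kind, 0.7))
    expect_equal(out, u, tolerance = 1e-13)
  }
})

test_that("each sub-step and the composed generation preserve the simplex", {
  land <- make_percolation(4, 0.6, seed = 8)
  set.seed(8)
  f <- random_simplex(16)
  for (kind in c("uniform", "one_point", "communal")) {
    out <- generation(f, land, 0.02, recombination_scheme(kind, 0.5))
    expect_true(all(out >= 0))
    expect_equal(sum(out), 1, tolerance = 1e-12)
  }
})

test_that("the non-recombining stationary state is unique across initial
           conditions and matches the direct eigen solution", {
  land <- make_mesa(4, 1)
  sch <- recombination_scheme("uniform", 0)
  ref <- stationary_state("uniform", land, 0.01, sch)  # eigen path
  set.seed(4)
  for (i in 1:5) {
    init <- random_simplex(16)
    st <- stationary_state(init, land, 0.01, sch, tol = 1e-12,
                           method = "iterate")
    expect_true(st$converged)
    expect_lt(max(abs(st$f - ref$f)), 1e-8)
  }
  # same agreement on a rugged landscape
  perc <- make_percolation(5, 0.5, seed = 31)
  e <- stationary_state("uniform", perc, 0.005, sch)
  it <- stationary_state("uniform", perc, 0.005, sch, tol = 1e-13,
                         method = "iterate", max_iter = 2e5)
  expect_lt(max(abs(e$f - it$f)), 1e-7)
})

test_that("robustness at stationarity is invariant under relabeling of loci", {
  land <- make_percolation(4, 0.6, seed = 12)
  L <- 4
  perm <- vapply(0:(2^L - 1L), function(i)
    genotype_index(rev(genotype_bits(i, L))), integer(1))
  land_perm <- fitness_landscape(land$w[order(perm)], L)
  for (r in c(0, 0.8)) {
    sch <- recombination_scheme("uniform", r)
    a <- stationary_state("uniform", land, 0.01, sch)
    b <- stationary_state("uniform", land_perm, 0.01, sch)
    expect_equal(a$robustness, b$robustness, tolerance = 1e-9)
  }
})

test_that("population robustness weights viable genotypes by frequency", {
  land <- make_mesa(5, 2)
  f <- numeric(32); f[1] <- 1               # delta on the plateau interior
  expect_equal(population_robustness(land, f), 1)
  # two-locus stationary state: m = f0 + f1/2
  st <- stationary_state("uniform", make_mesa(2, 1), 0.02,
                         recombination_scheme("one_point", 0.6), tol = 1e-14)
  expect_equal(population_robustness(make_mesa(2, 1), st$f),
               st$f[1] + (st$f[2] + st$f[3]) / 2, tolerance = 1e-14)
})

test_that("entropy vanishes for monomorphic and is L log 2 for uniform states", {
  f <- numeric(16); f[5] <- 1
  expect_equal(population_entropy(f), 0)
  expect_equal(population_entropy(rep(1 / 16, 16)), 4 * log(2))
  # strong recombination at small mutation rate concentrates the population
  st <- stationary_state("uniform", make_mesa(2, 1), 1e-4,
                         recombination_scheme("one_point", 1), tol = 1e-14)
  expect_lt(population_entropy(st$f), 0.15)
})

test_that("robustness rises steeply with recombination rate on a mesa", {
  land <- make_mesa(5, 2)
  sw <- sweep_r_warmstart(land, 0.001, r_grid = c(0, 0.1, 0.3, 1),
                          tol = 1e-11)
  expect_length(sw$m_values, 4)
  expect_length(sw$r_grid, 4)
  expect_true(all(sw$converged))
  expect_true(all(diff(sw$m_values) > 0))
  expect_gt(sw$m_values[4], 0.95)            # near-saturation at r = 1
  expect_gt(sw$m_values[2], sw$m_values[1])  # strong gain already at small r
  df <- as.data.frame(sw)
  expect_equal(names(df), c("r", "m", "mean_fitness", "iterations", "converged"))
})

test_that("the reset protocol on a single grid point equals the unique
           non-recombining solution", {
  land <- make_percolation(5, 0.5, seed = 2)
  sw <- sweep_r_reset(land, 0.005, r_grid = 0)
  ref <- stationary_state("uniform", land, 0.005,
                          recombination_scheme("uniform", 0))
  expect_equal(sw$m_values[1], ref$robustness, tolerance = 1e-10)
  expect_equal(sw$protocol, "reset")
})

test_that("robustness increases monotonically along the reset sweep on the
           synthetic graded landscape", {
  land <- make_aniger_standin(seed = 2)
  sw <- sweep_r_reset(land, 0.005, r_grid = c(0, 0.4, 1), tol = 1e-10)
  expect_true(all(diff(sw$m_values) >= -1e-8))
})

test_that("localized starts find a unique state without recombination and
           multiple states with it", {
  land <- make_percolation(5, 0.4, seed = 3)
  sc0 <- multistability_scan(land, 0.01, recombination_scheme("uniform", 0),
                             tol = 1e-12)
  expect_equal(length(sc0$robustness), 1L)
  expect_equal(sc0$n_starts, sum(genotype_robustness(land) != 0))
  sc1 <- multistability_scan(land, 0.01, recombination_scheme("uniform", 1),
                             tol = 1e-11)
  expect_gte(length(sc1$robustness), 2L)
  expect_equal(sum(sc1$basin_counts) + sc1$n_extinct, sc1$n_starts)
  # this realization shows recombination lowering the robustness of one
  # stationary state below the non-recombining value while the average over
  # starts is higher
  m_r0 <- stationary_state("uniform", land, 0.01,
                           recombination_scheme("uniform", 0))$robustness
  expect_lt(min(sc1$robustness), m_r0)
  expect_gt(sc1$mean_robustness, m_r0)
})
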