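# Selection -> mutation -> recombination generation map, stationary-state
# solvers, population statistics, and the r-sweep and multistability
# protocols.

#' Selection step
#'
#' Reweights a frequency vector by fitness: `q = w * f / wbar` with
#' `wbar = sum(w * f)`. A population supported entirely on lethal genotypes
#' has `wbar = 0` and is extinct, which is a hard error.
#'
#' @param f frequency vector over `2^L` genotypes.
#' @param land a [fitness_landscape()].
#' @return post-selection frequency vector.
#' @export
selection_step <- function(f, land) {
  .check_landscape(land)
  .check_freq(f, land$L)
  wbar <- sum(land$w * f)
  if (wbar <= 0)
    stop("extinction: population supported on lethal genotypes only",
         call. = FALSE)
  land$w * f / wbar
}

# compiled one-generation closure; resolves scheme dispatch and caches index
# tables outside the iteration loop
.generation_fun <- function(land, mu, scheme) {
  L <- land$L
  w <- land$w
  r <- scheme$r
  kind <- scheme$kind
  flips <- .flip_table(L)
  if (kind == "uniform" && r > 0) .uniform_pairs(L)  # warm the cache
  function(f) {
    wbar <- sum(w * f)
    if (wbar <= 0)
      stop("extinction: population supported on lethal genotypes only",
           call. = FALSE)
    p <- w * f / wbar
    for (i in seq_len(L)) p <- (1 - mu) * p + mu * p[flips[, i]]
    if (r > 0) {
      mixed <- switch(kind,
        uniform = .uniform_map1(p, L),
        one_point = .onepoint_map1(p, L),
        communal = .le_projection(p, L))
      p <- (1 - r) * p + r * mixed
    }
    .renorm(p)
  }
}

#' One full generation of the deterministic dynamics
#'
#' Applies selection ([selection_step()]), symmetric mutation
#' ([apply_mutation()]) and recombination ([recombination_step()]) in that
#' order and returns the next-generation frequency vector (renormalized to
#' absorb floating-point drift).
#'
#' @param f frequency vector.
#' @param land a [fitness_landscape()].
#' @param mu per-locus mutation rate.
#' @param scheme a [recombination_scheme()].
#' @return next-generation frequency vector.
#' @export
generation <- function(f, land, mu, scheme) {
  .check_landscape(land)
  .check_scheme(scheme)
  .check_prob(mu, "mu")
  .check_freq(f, land$L)
  .generation_fun(land, mu, scheme)(f)
}

#' Stationary state of the deterministic dynamics
#'
#' Fixed-point iteration of [generation()] until the max-norm change per
#' generation drops below `tol` or `max_iter` is reached. In the absence of
#' recombination the stationary state is unique (the leading eigenvector of
#' the mutation-selection operator); with recombination the dynamics is
#' nonlinear and the reached state may depend on the initial condition.
#' Non-convergence is reported in the result, not raised; extinction is an
#' error.
#'
#' @param init initial frequency vector, or `"uniform"`.
#' @param land a [fitness_landscape()].
#' @param mu per-locus mutation rate.
#' @param scheme a [recombination_scheme()].
#' @param tol max-norm convergence tolerance per generation.
#' @param max_iter iteration cap.
#' @param method `"auto"` (default), `"iterate"` or `"eigen"`. Without
#'   recombination the generation map is linear and its unique fixed point
#'   is the Perron eigenvector of the mutation-selection operator; `"auto"`
#'   computes it directly by a symmetric eigendecomposition (the
#'   power-iteration limit) when `r = 0`, which sidesteps the very slow
#'   relaxation of landscapes with several nearly degenerate neutral
#'   clusters, and iterates otherwise. `"iterate"` forces plain fixed-point
#'   iteration from `init`.
#' @return an object of class `stationary_result`: list with `f` (stationary
#'   frequencies), `iterations`, `residual`, `converged`, `robustness`,
#'   `mean_fitness`.
#' @export
stationary_state <- function(init, land, mu, scheme,
                             tol = 1e-13, max_iter = 1e6,
                             method = c("auto", "iterate", "eigen")) {
  .check_landscape(land)
  .check_scheme(scheme)
  .check_prob(mu, "mu")
  method <- match.arg(method)
  L <- land$L
  if (identical(init, "uniform")) init <- rep(1 / 2^L, 2^L)
  .check_freq(init, L)
  if (method == "eigen" || (method == "auto" && scheme$r == 0 && L <= 12)) {
    if (scheme$r > 0)
      stop("'eigen' method applies only without recombination", call. = FALSE)
    if (sum(land$w * init) <= 0)
      stop("extinction: population supported on lethal genotypes only",
           call. = FALSE)
    return(.stationary_eigen(land, mu, tol))
  }
  step <- .generation_fun(land, mu, scheme)
  f <- init
  res <- Inf
  it <- 0L
  warmup <- if (method == "auto") min(2000, max_iter) else max_iter
  since_newton <- 0L
  while (it < max_iter) {
    it <- it + 1L
    since_newton <- since_newton + 1L
    f_new <- step(f)
    res <- max(abs(f_new - f))
    f <- f_new
    if (res < tol) break
    if (method == "auto" && since_newton >= warmup) {
      # slow relaxation (e.g. near-degenerate neutral clusters competing at
      # rate O(mu^2)): refine the current iterate by Newton's method on the
      # fixed-point residual
      nf <- .newton_refine(f, step, tol)
      it <- it + nf$evals
      since_newton <- 0L
      if (nf$residual < res) {
        f <- nf$f; res <- nf$residual
        if (res < tol) break
      }
    }
  }
  structure(list(f = f, iterations = it, residual = res,
                 converged = res < tol,
                 robustness = population_robustness(land, f),
                 mean_fitness = sum(land$w * f)),
            class = "stationary_result")
}

# Newton iteration for G(f) = step(f) - f = 0 on the simplex; the Jacobian
# is formed by forward differences and the linear system is augmented with
# the constraint sum(delta) = 0. Trial points are projected back onto the
# simplex and oversized steps are damped; the best iterate by residual is
# returned (the caller keeps it only if it improves on plain iteration).
.newton_refine <- function(f, step, tol, max_newton = 40L, h = 1e-8) {
  n <- length(f)
  evals <- 1L
  best <- list(f = f, residual = max(abs(step(f) - f)))
  for (nt in seq_len(max_newton)) {
    Fs <- step(f)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      fp <- f
      fp[j] <- fp[j] + h
      J[, j] <- (step(fp) - Fs) / h
    }
    evals <- evals + n + 1L
    A <- rbind(J - diag(n), rep(1, n))
    delta <- tryCatch(qr.solve(A, c(-(Fs - f), 0)),
                      error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    dmax <- max(abs(delta))
    if (dmax > 1) delta <- delta / dmax
    f_try <- pmax(f + delta, 0)
    s <- sum(f_try)
    if (s <= 0) break
    f_try <- f_try / s
    res_try <- tryCatch(max(abs(step(f_try) - f_try)),
                        error = function(e) NA_real_)
    evals <- evals + 1L
    if (!is.finite(res_try)) break
    f <- f_try
    if (res_try < best$residual) best <- list(f = f, residual = res_try)
    if (res_try < tol) break
  }
  best$evals <- evals
  best
}

# direct stationary state for the linear r = 0 dynamics: the fixed point of
# f -> U W f / wbar is the leading eigenvector of U W. With
# W = diag(w), U W is similar to the symmetric W^(1/2) U W^(1/2), whose
# leading eigenvector z (restricted to the viable support) gives the
# post-selection state y = W^(1/2) z and the stationary post-mutation state
# f* = U y / sum(U y).
.stationary_eigen <- function(land, mu, tol) {
  L <- land$L
  w <- land$w
  sup <- which(w > 0)
  if (length(sup) == 0)
    stop("extinction: landscape has no viable genotype", call. = FALSE)
  U <- mutation_matrix(L, mu)
  sw <- sqrt(w[sup])
  S <- U[sup, sup, drop = FALSE] * (sw %o% sw)
  ev <- eigen(S, symmetric = TRUE)
  z <- ev$vectors[, which.max(ev$values)]
  if (sum(z) < 0) z <- -z
  z <- pmax(z, 0)
  y <- numeric(2^L)
  y[sup] <- sw * z
  f <- as.vector(U %*% y)
  f <- f / sum(f)
  f_next <- .generation_fun(land, mu, recombination_scheme("uniform", 0))(f)
  res <- max(abs(f_next - f))
  structure(list(f = f, iterations = 0L, residual = res,
                 converged = res < max(tol, 1e-12),
                 robustness = population_robustness(land, f),
                 mean_fitness = sum(land$w * f)),
            class = "stationary_result")
}

#' @export
print.stationary_result <- function(x, ...) {
  cat(sprintf(
    "Stationary state: %s after %d iterations (residual %.3g)\n  robustness m = %.6f, mean fitness = %.6f\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$residual, x$robustness, x$mean_fitness))
  invisible(x)
}

#' Population mutational robustness
#'
#' `m = sum_{sigma in V} m_sigma * f_sigma`: the robustness of viable
#' genotypes weighted by their frequencies. Mass sitting on lethal genotypes
#' contributes zero (no renormalization over the viable set).
#'
#' @param land a [fitness_landscape()].
#' @param f frequency vector.
#' @return robustness in `[0, 1]`.
#' @export
population_robustness <- function(land, f) {
  .check_landscape(land)
  m <- genotype_robustness(land)
  sum(m[land$w > 0] * f[land$w > 0])
}

#' Shannon entropy of a genotype frequency distribution
#'
#' `S = -sum f log f` (natural log, `0 log 0 = 0`). Zero for a monomorphic
#' population, `L log 2` for the uniform distribution.
#'
#' @param f frequency vector.
#' @return non-negative entropy.
#' @export
population_entropy <- function(f) {
  pos <- f > 0
  -sum(f[pos] * log(f[pos]))
}

.check_r_grid <- function(r_grid) {
  if (length(r_grid) < 1 || r_grid[1] != 0 || any(diff(r_grid) <= 0) ||
      any(r_grid < 0) || any(r_grid > 1))
    stop("'r_grid' must start at 0, be strictly increasing and stay in [0, 1]",
         call. = FALSE)
  r_grid
}

.sweep_r <- function(land, mu, r_grid, kind, warm_start, tol, max_iter) {
  .check_landscape(land)
  .check_r_grid(r_grid)
  f <- rep(1 / 2^land$L, 2^land$L)
  states <- vector("list", length(r_grid))
  for (i in seq_along(r_grid)) {
    init <- if (warm_start && i > 1) states[[i - 1]]$f else rep(1 / 2^land$L, 2^land$L)
    states[[i]] <- stationary_state(init, land, mu,
                                    recombination_scheme(kind, r_grid[i]),
                                    tol = tol, max_iter = max_iter)
  }
  structure(list(
    r_grid = r_grid,
    m_values = vapply(states, `[[`, numeric(1), "robustness"),
    mean_fitness = vapply(states, `[[`, numeric(1), "mean_fitness"),
    iterations = vapply(states, `[[`, integer(1), "iterations"),
    converged = vapply(states, `[[`, logical(1), "converged"),
    states = states,
    protocol = if (warm_start) "warm_start" else "reset"),
    class = "sweep_result")
}

#' Robustness sweep over recombination rates
#'
#' `sweep_r_warmstart()` follows the adiabatic protocol: start from the
#' uniform distribution, converge at `r = 0`, then increase `r` along the
#' grid using each stationary state as the initial condition for the next
#' rate. The branch traced this way is the one smoothly connected to the
#' unique non-recombining state. `sweep_r_reset()` instead restarts from the
#' uniform distribution before every grid point, which on landscapes with
#' fitness peaks avoids peak trapping and can land on different branches.
#'
#' @param land a [fitness_landscape()].
#' @param mu per-locus mutation rate.
#' @param r_grid strictly increasing recombination rates starting at 0
#'   (by default ending at 1 in increments of 0.02).
#' @param kind recombination scheme kind (`"uniform"`, `"one_point"`,
#'   `"communal"`).
#' @param tol,max_iter convergence control, as in [stationary_state()].
#' @return an object of class `sweep_result`: list with `r_grid`,
#'   `m_values`, `mean_fitness`, `iterations`, `converged`, the per-point
#'   `states`, and `protocol`.
#' @export
sweep_r_warmstart <- function(land, mu, r_grid = seq(0, 1, by = 0.02),
                              kind = "uniform", tol = 1e-13, max_iter = 1e6) {
  .sweep_r(land, mu, r_grid, kind, warm_start = TRUE, tol, max_iter)
}

#' @rdname sweep_r_warmstart
#' @export
sweep_r_reset <- function(land, mu, r_grid = seq(0, 1, by = 0.02),
                          kind = "uniform", tol = 1e-13, max_iter = 1e6) {
  .sweep_r(land, mu, r_grid, kind, warm_start = FALSE, tol, max_iter)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Recombination-rate sweep (%s protocol), %d grid points\n",
              x$protocol, length(x$r_grid)))
  print(utils::head(data.frame(r = x$r_grid, m = x$m_values,
                               mean_fitness = x$mean_fitness,
                               converged = x$converged), 10))
  if (length(x$r_grid) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(r = x$r_grid, m = x$m_values, mean_fitness = x$mean_fitness,
             iterations = x$iterations, converged = x$converged)
}

#' Enumerate stationary states from localized initial conditions
#'
#' Starts the dynamics from a delta distribution on every genotype with
#' nonzero robustness (`m_sigma != 0`), converges each run, and clusters the
#' resulting stationary states (two states are the same if their max-norm
#' distance is below `cluster_tol`). Without recombination all starts reach
#' the unique state; with recombination the map is nonlinear and distinct
#' states with different robustness may coexist. Starts that go extinct
#' (delta mass on a lethal genotype with only lethal neighbours, for
#' instance) are skipped and tallied.
#'
#' @param land a neutral [fitness_landscape()].
#' @param mu per-locus mutation rate.
#' @param scheme a [recombination_scheme()].
#' @param cluster_tol max-norm distance under which two stationary states are
#'   identified.
#' @param tol,max_iter convergence control.
#' @return list with `states` (one [stationary_state()] result per distinct
#'   state), `robustness` (per distinct state), `basin_counts` (starts that
#'   reached each state), `mean_robustness` (average over all non-extinct
#'   starts), `n_starts`, `n_extinct`.
#' @export
multistability_scan <- function(land, mu, scheme, cluster_tol = 1e-6,
                                tol = 1e-13, max_iter = 1e6) {
  .check_landscape(land)
  m_sigma <- genotype_robustness(land)
  starts <- which(m_sigma != 0) - 1L
  reps <- list()
  basin <- integer(0)
  robust_all <- numeric(0)
  n_extinct <- 0L
  for (s in starts) {
    f0 <- numeric(2^land$L); f0[s + 1L] <- 1
    st <- tryCatch(stationary_state(f0, land, mu, scheme,
                                    tol = tol, max_iter = max_iter),
                   error = function(e) NULL)
    if (is.null(st)) { n_extinct <- n_extinct + 1L; next }
    robust_all <- c(robust_all, st$robustness)
    hit <- 0L
    for (j in seq_along(reps)) {
      if (max(abs(st$f - reps[[j]]$f)) < cluster_tol) { hit <- j; break }
    }
    if (hit == 0L) { reps[[length(reps) + 1L]] <- st; basin <- c(basin, 1L) }
    else basin[hit] <- basin[hit] + 1L
  }
  list(states = reps,
       robustness = vapply(reps, `[[`, numeric(1), "robustness"),
       basin_counts = basin,
       mean_robustness = if (length(robust_all)) mean(robust_all) else NaN,
       n_starts = length(starts),
       n_extinct = n_extinct)
}
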