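# Closed-form and semi-analytic solutions for the two-locus model: three
# viable genotypes (00, 01, 10) of unit fitness and a lethal double mutant
# (11). The effective recombination parameter rho unifies the schemes at
# L = 2: rho = r for one-point crossover and rho = r/2 for uniform
# crossover (a coincidence special to two loci).
#
# At stationarity the problem reduces to a cubic in q0, the post-selection
# frequency of the wild type:
#   0 = rho/4 (1-2mu)^2 (1-q0)^2 (1+q0)
#       + mu [1 - 2 q0 - q0^2 - mu (1 - 2 q0)(1 + q0)].

.twolocus_cubic_coefs <- function(mu, rho) {
  a <- rho / 4 * (1 - 2 * mu)^2
  # a (1 - q - q^2 + q^3) + mu [(1 - mu) + (mu - 2) q + (2 mu - 1) q^2]
  c(a + mu * (1 - mu),
    -a + mu * (mu - 2),
    -a + mu * (2 * mu - 1),
    a)
}

#' Map a scheme recombination rate to the two-locus parameter rho
#'
#' @param r recombination rate in `[0, 1]`.
#' @param kind `"one_point"` (`rho = r`) or `"uniform"` (`rho = r/2`).
#' @return `rho` in `[0, 1]`.
#' @export
rho_from_r <- function(r, kind = c("one_point", "uniform")) {
  kind <- match.arg(kind)
  .check_prob(r, "r")
  if (kind == "one_point") r else r / 2
}

#' Stationary post-selection wild-type frequency of the two-locus model
#'
#' Solves the stationarity cubic for `q0`, keeping the unique root in
#' `[0, 1]`. For `rho = 0` the cubic degenerates to a quadratic with root
#' `q0 -> sqrt(2) - 1` as `mu -> 0`; for `rho = 1`, `q0 -> 1`.
#'
#' @param mu per-locus mutation rate in `(0, 1/2]`.
#' @param rho effective recombination parameter in `[0, 1]` (see
#'   [rho_from_r()]).
#' @return `q0` in `[0, 1]`.
#' @export
solve_q0 <- function(mu, rho) {
  if (!is.numeric(mu) || mu <= 0 || mu > 0.5)
    stop("'mu' must lie in (0, 1/2]", call. = FALSE)
  .check_prob(rho, "rho")
  co <- .twolocus_cubic_coefs(mu, rho)
  roots <- polyroot(co)
  real <- Re(roots[abs(Im(roots)) < 1e-9])
  inside <- real[real >= -1e-12 & real <= 1 + 1e-12]
  if (length(inside) == 0)
    stop("no root of the stationarity cubic in [0, 1]", call. = FALSE)
  if (length(inside) > 1) {
    # keep the branch continuously connected to the rho = 0 solution
    q0_ref <- solve_q0(mu, 0)
    inside <- inside[which.min(abs(inside - q0_ref))]
  }
  min(max(inside, 0), 1)
}

#' Stationary frequencies of the two-locus model
#'
#' Reconstructs the full stationary solution from `q0`: the post-mutation
#' lumped frequencies
#' `p0 = mu(1-mu) + (1-mu)(1-2mu) q0`,
#' `p1 = 1 - 2mu + 2mu^2 - (1-2mu)^2 q0`,
#' `p2 = mu(1-mu) - mu(1-2mu) q0`,
#' the linkage disequilibrium `D = -(1-2mu)^2 (1-q0)^2 / 4`, and the
#' post-recombination genotype frequencies
#' `f00 = p0 - rho D`, `f01 = f10 = (p1 + 2 rho D)/2`, `f11 = p2 - rho D`.
#' At `rho = 1` the stationary state is at linkage equilibrium
#' (`f00 f11 = f01 f10`).
#'
#' @inheritParams solve_q0
#' @return an object of class `twolocus_solution`: list with `mu`, `rho`,
#'   `q0`, `p` (lumped post-mutation frequencies), `D`, `f` (named genotype
#'   frequencies `f00`, `f01`, `f10`, `f11`), `m` (robustness).
#' @export
twolocus_stationary <- function(mu, rho) {
  q0 <- solve_q0(mu, rho)
  p0 <- mu * (1 - mu) + (1 - mu) * (1 - 2 * mu) * q0
  p1 <- 1 - 2 * mu + 2 * mu^2 - (1 - 2 * mu)^2 * q0
  p2 <- mu * (1 - mu) - mu * (1 - 2 * mu) * q0
  D <- -(1 - 2 * mu)^2 * (1 - q0)^2 / 4
  f0 <- p0 - rho * D
  f1 <- p1 + 2 * rho * D
  f2 <- p2 - rho * D
  structure(list(mu = mu, rho = rho, q0 = q0,
                 p = c(p0 = p0, p1 = p1, p2 = p2), D = D,
                 f = c(f00 = f0, f01 = f1 / 2, f10 = f1 / 2, f11 = f2),
                 m = f0 + f1 / 2),
            class = "twolocus_solution")
}

#' @export
print.twolocus_solution <- function(x, ...) {
  cat(sprintf("Two-locus stationary state (mu = %g, rho = %g)\n", x$mu, x$rho))
  cat(sprintf("  q0 = %.8f, m = %.8f, D = %.3g\n", x$q0, x$m, x$D))
  cat(sprintf("  f = (%.6f, %.6f, %.6f, %.6f)\n",
              x$f[1], x$f[2], x$f[3], x$f[4]))
  invisible(x)
}

#' Closed-form stationary frequencies at the extreme recombination rates
#'
#' Exact radicals for the stationary genotype frequencies with no
#' recombination (`rho = 0`) and with full one-point crossover (`rho = 1`,
#' linkage equilibrium restored every generation). Used as independent
#' cross-checks of the cubic route.
#'
#' @param mu per-locus mutation rate in `(0, 1/2]`.
#' @return named vector `c(f00, f01, f10, f11)`.
#' @export
twolocus_exact_rho0 <- function(mu) {
  rad <- sqrt(8 - 16 * mu + 9 * mu^2)
  f00 <- (1 - mu) / 2 * rad - (2 - 5 * mu + 3 * mu^2) / 2
  f01 <- (4 - 9 * mu + 6 * mu^2) / 4 - (1 - 2 * mu) / 4 * rad
  f11 <- mu / 2 * (4 - 3 * mu - rad)
  c(f00 = f00, f01 = f01, f10 = f01, f11 = f11)
}

#' @rdname twolocus_exact_rho0
#' @export
twolocus_exact_rho1 <- function(mu) {
  s <- sqrt(mu^2 + 4 * mu)
  a <- (2 + mu - s) / 2   # stationary frequency of allele 0 per locus
  b <- (s - mu) / 2
  c(f00 = a^2, f01 = a * b, f10 = a * b, f11 = b^2)
}

#' Mutational robustness of the two-locus model
#'
#' Exact stationary robustness `m = f00 + f01 = 1/2 + (1 - 2 mu) q0 / 2`
#' from the cubic, together with the closed forms at the extremes,
#' `m(mu, 0) = (mu + sqrt(8 - 16 mu + 9 mu^2)) / 4` and
#' `m(mu, 1) = (2 + mu - sqrt(mu^2 + 4 mu)) / 2`, and the small-parameter
#' expansions: for `rho << mu`, `m ~ 1/2 + (3 - 2 sqrt(2))/sqrt(2) * l`
#' with `l = rho/(4 mu)` (up to an `O(mu)` correction), and for
#' `rho >> mu`, `m ~ 1 - sqrt(mu / rho)`.
#'
#' @inheritParams solve_q0
#' @return list with `m` (exact), `m_rho0`, `m_rho1` (closed-form
#'   extremes), `m_weak` (`rho << mu` expansion), `m_strong`
#'   (`rho >> mu` expansion).
#' @export
robustness_twolocus <- function(mu, rho) {
  q0 <- solve_q0(mu, rho)
  l <- rho / (4 * mu)
  list(m = 1 / 2 + (1 - 2 * mu) * q0 / 2,
       m_rho0 = (mu + sqrt(8 - 16 * mu + 9 * mu^2)) / 4,
       m_rho1 = (2 + mu - sqrt(mu^2 + 4 * mu)) / 2,
       m_weak = 1 / 2 + (3 - 2 * sqrt(2)) / sqrt(2) * l -
         (1 / sqrt(2) - 1 / 4) * mu,
       m_strong = if (rho > 0) 1 - sqrt(mu / rho) else NA_real_)
}

#' Critical recombination rate of the two-locus model
#'
#' The recombination parameter `rho_c` at which recombination exactly
#' compensates the mutational loss of robustness, i.e.
#' `m(mu, rho_c) = 1/sqrt(2)`, the `mu -> 0` robustness of the
#' non-recombining model. For small `mu`, `rho_c = 2 (5 + 4 sqrt(2)) mu^2`
#' (about `21.3 mu^2`). The numerical value is found by bisection on the
#' exact cubic; analytic and numerical values agree as `mu -> 0`.
#'
#' @param mu per-locus mutation rate (the expansion is accurate for
#'   `mu` up to about `1e-2`).
#' @return list with `analytic`, `numerical`, and `constant`
#'   (`2 (5 + 4 sqrt(2))`).
#' @export
critical_rho <- function(mu) {
  target <- 1 / sqrt(2)
  g <- function(rho) robustness_twolocus(mu, rho)$m - target
  if (g(0) >= 0) stop("robustness at rho = 0 already exceeds the target;
 'mu' too small to resolve", call. = FALSE)
  if (g(1) <= 0) stop("no crossing of the target robustness in rho [0, 1]",
                      call. = FALSE)
  root <- stats::uniroot(g, c(0, 1), tol = 1e-16)$root
  list(analytic = 2 * (5 + 4 * sqrt(2)) * mu^2,
       numerical = root,
       constant = 2 * (5 + 4 * sqrt(2)))
}

#' Two-locus recombination weights
#'
#' `lambda = (3/4 + rho/4, 3/4 - rho/4, 3/4 - rho/4, rho/4)` for genotypes
#' (00, 01, 10, 11); their sum is `9/4 = |V|^2 / 2^L` for every `rho`. The
#' wild type (00) is the recombination center for all `rho > 0`.
#'
#' @param rho effective recombination parameter in `[0, 1]`.
#' @return named numeric vector of length 4.
#' @export
weights_twolocus <- function(rho) {
  .check_prob(rho, "rho")
  c(l00 = 3 / 4 + rho / 4, l01 = 3 / 4 - rho / 4,
    l10 = 3 / 4 - rho / 4, l11 = rho / 4)
}
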