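# Evolutionary stability of a candidate strategy.
#
# Three conditions are verified for a resident strategy p* against a mutant
# strategy p:
#   (1) p* earns at least as much as p against the resident population
#       (Nash condition);
#   (2) where (1) is tight, p* earns strictly more against the mutant
#       population than the mutant earns against itself;
#   (3) for a small invading fraction eps, p* strictly out-earns p in the
#       mixed population q = eps*p + (1-eps)*p*.
# (1) and (2) together are equivalent to (3) for sufficiently small eps;
# the numeric check below evaluates all three over explicit grids.

# Core checker over arbitrary pure-strategy payoff curves; also used by the
# randomized property tests on generic affine games.
ess_conditions <- function(p_star, payoff_T_curve, payoff_U_curve,
                           mutants, epsilons, tol = 1e-12) {
  if (length(mutants) == 0L || length(epsilons) == 0L)
    stop("mutant and epsilon grids must be nonempty", call. = FALSE)
  if (any(epsilons <= 0) || any(epsilons >= 1))
    stop("epsilon values must lie in (0, 1)", call. = FALSE)
  warnings <- character(0)
  if (length(unique(mutants)) < 2L)
    warnings <- c(warnings, "degenerate mutant grid (single point)")

  payoff <- function(p, q)
    p * payoff_T_curve(q) + (1 - p) * payoff_U_curve(q)
  mut <- mutants[abs(mutants - p_star) > tol]
  if (length(mut) == 0L)
    warnings <- c(warnings,
                  "no mutant distinct from the candidate; conditions vacuous")

  # Inequality (1) at the resident state q = p*
  d1 <- payoff(p_star, p_star) - vapply(mut, payoff, numeric(1), q = p_star)
  nash_ok <- all(d1 >= -tol)
  strict <- length(mut) > 0L && all(d1 > tol)

  # Inequality (2) at the mutants where (1) is tight
  tight <- mut[abs(d1) <= tol]
  d2 <- vapply(tight, function(m) payoff(p_star, m) - payoff(m, m),
               numeric(1))
  second_ok <- all(d2 > tol)

  # Inequality (3) over the (mutant, epsilon) product grid
  epsilons <- sort(epsilons)
  pass_by_eps <- vapply(epsilons, function(eps) {
    qmix <- eps * mut + (1 - eps) * p_star
    all(payoff(p_star, qmix) - vapply(seq_along(mut), function(j)
      payoff(mut[j], qmix[j]), numeric(1)) > 0)
  }, logical(1))
  invasion_ok <- all(pass_by_eps)
  # largest tested eps below which every smaller tested eps also resists
  # invasion: a tested lower bound for the true invasion barrier
  n_ok <- if (all(pass_by_eps)) length(epsilons)
          else min(which(!pass_by_eps)) - 1L
  barrier <- if (n_ok == 0L) 0 else epsilons[n_ok]

  structure(
    list(candidate = p_star, nash_ok = nash_ok, strict = strict,
         second_condition_ok = second_ok, invasion_ok = invasion_ok,
         epsilon_grid = epsilons, barrier_estimate = barrier,
         mutant_grid = mutants, warnings = warnings),
    class = "ess_check")
}

#' Verify evolutionary stability of a candidate strategy
#'
#' Checks, for the prescribing game, whether the candidate resists invasion
#' by rare mutants: the Nash condition against the resident population, the
#' tie-breaking second condition where the Nash condition is tight, and the
#' invasion condition over an explicit grid of invading fractions. The
#' reported `barrier_estimate` is the largest tested invading fraction up
#' to which every tested mutant is repelled — a numeric lower bound for the
#' true invasion barrier, never a claim of its exact value.
#'
#' For the baseline game the all-treat strategy `p* = 1` passes every
#' condition: against any resident state `q < 1` it is the strict best
#' response, at `q = 1` all strategies tie but the second condition holds,
#' and any mutant mixture is strictly out-earned, so small deviations are
#' self-correcting.
#'
#' @param candidate the resident strategy `p*` in `[0, 1]`.
#' @param params an `abx_game`.
#' @param mutant_grid mutant strategies to test against.
#' @param epsilon_grid invading fractions in (0, 1) to test.
#' @param tol payoff-equality tolerance.
#' @return An object of class `ess_check` with fields `candidate`,
#'   `nash_ok`, `strict`, `second_condition_ok`, `invasion_ok`,
#'   `epsilon_grid`, `barrier_estimate`, `mutant_grid`, `warnings`.
#' @examples
#' check_ess(1, prescribing_game(phi = 0.5))
#' @export
check_ess <- function(candidate, params,
                      mutant_grid = seq(0, 1, length.out = 21),
                      epsilon_grid = 10^(-6:-1), tol = 1e-12) {
  params <- as_game(params)
  check_p(candidate)
  check_p(mutant_grid)
  ess_conditions(candidate,
                 function(q) pure_payoffs(q, params)$payoff_T,
                 function(q) pure_payoffs(q, params)$payoff_U,
                 mutants = mutant_grid, epsilons = epsilon_grid, tol = tol)
}

#' @export
print.ess_check <- function(x, ...) {
  cat(sprintf("ESS check for candidate p* = %g\n", x$candidate))
  cat("  Nash condition:    ", x$nash_ok,
      if (x$strict) " (strict)" else " (tight against some mutants)", "\n",
      sep = "")
  cat("  second condition:  ", x$second_condition_ok, "\n", sep = "")
  cat("  invasion resisted: ", x$invasion_ok,
      sprintf("  (tested barrier >= %g)", x$barrier_estimate), "\n",
      sep = "")
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
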