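test_that("best response is treat below the crossing, anything at a tie", {
  g <- baseline_game(0.5)
  expect_equal(best_response(0.5, g), list(type = "point", p = 1))
  expect_equal(best_response(1, g), list(type = "interval", p = c(0, 1)))
  # beyond the crossing with side effects, withholding is strictly better
  gc <- crossing_game(q_prime = 0.5, cost = 0.05, phi = 0.5)
  expect_equal(best_response(0.9, gc), list(type = "point", p = 0))
  expect_equal(best_response(0.1, gc)$p, 1)
})

test_that("best response agrees with brute-force argmax over a p grid", {
  set.seed(7)
  p_grid <- seq(0, 1, by = 1e-4)
  for (g in list(baseline_game(0.5), residual_game(), crossing_game())) {
    for (q in runif(100)) {
      br <- best_response(q, g)
      vals <- payoff_mixed(p_grid, q, g)
      best_p <- p_grid[which.max(vals)]
      if (br$type == "point") {
        expect_equal(best_p, br$p)
      } else {
        # a tie: every strategy within numerical noise of the maximum
        expect_lt(diff(range(vals)), 1e-10)
      }
    }
  }
})

test_that("treat is dominant; strictly so under residual efficacy", {
  d <- is_dominant(1, baseline_game(0.5))
  expect_true(d$dominant)
  expect_true(d$strict)
  expect_false(d$strict_everywhere)  # tie at q = 1
  dr <- is_dominant(1, residual_game(0.5, 0.2))
  expect_true(dr$dominant)
  expect_true(dr$strict_everywhere)
  expect_false(is_dominant(0, baseline_game(0.5))$dominant)
  expect_false(is_dominant(1, crossing_game(cost = 0.05))$dominant)
  expect_error(is_dominant(1, baseline_game(), q_grid = numeric(0)),
               "nonempty")
})

test_that("symmetric Nash equilibrium is all-treat, unique for the baseline", {
  for (phi in seq(0.1, 1, by = 0.1)) {
    nash <- find_symmetric_nash(baseline_game(phi))
    expect_equal(nrow(nash), 1L)
    expect_equal(nash$p_star, 1)
    expect_true(nash$strict)
  }
  nr <- find_symmetric_nash(residual_game(0.5, 0.2))
  expect_equal(nr$p_star, 1)
  expect_true(nr$strict)
  # side effects create an interior equilibrium where the curves cross
  nc <- find_symmetric_nash(crossing_game(q_prime = 0.5, cost = 0.05))
  expect_true(any(abs(nc$p_star - 0.45) < 1e-8))
  expect_false(any(nc$p_star == 1))
})

test_that("all-treat passes every evolutionary-stability condition", {
  g <- baseline_game(0.5)
  res <- check_ess(1, g, mutant_grid = c(0, 0.25, 0.5, 0.75),
                   epsilon_grid = 10^(-6:-1))
  expect_true(res$nash_ok)
  expect_false(res$strict)  # payoffs tie exactly at the all-treat state
  expect_true(res$second_condition_ok)
  expect_true(res$invasion_ok)
  expect_equal(res$barrier_estimate, 0.1)
  # never-treat is strictly dominated at its own resident state
  res0 <- check_ess(0, g)
  expect_false(res0$nash_ok)
  # ESS across the whole phi range at default grids
  for (phi in seq(0.05, 1, by = 0.05)) {
    r <- check_ess(1, baseline_game(phi))
    expect_true(r$nash_ok && r$second_condition_ok && r$invasion_ok)
  }
  # degenerate mutant grid is flagged, not an error
  expect_match(check_ess(1, g, mutant_grid = 0.5)$warnings, "degenerate")
  expect_error(check_ess(1, g, epsilon_grid = c(0.5, 1)), "epsilon")
})

test_that("cooperative optimum: half-treatment baseline, boundary or vertex otherwise", {
  for (phi in c(0.1, 0.5, 1)) {
    co <- cooperative_optimum(baseline_game(phi))
    expect_equal(co$q, 0.5)
    expect_equal(co$payoff, phi * (0.5 * 0.5 - 1))
  }
  # lambda below phi/2: full treatment is collectively best
  expect_equal(cooperative_optimum(residual_game(0.5, 0.2))$q, 1)
  # lambda above phi/2: interior vertex phi / (2 lambda)
  co2 <- cooperative_optimum(residual_game(0.5, 0.4))
  expect_equal(co2$q, 0.625)
  expect_equal(co2$q,
               grid_argmax(function(q)
                 symmetric_payoff(q, residual_game(0.5, 0.4))),
               tolerance = 2e-6)
  # generic 1-D optimizer as an independent cross-check
  for (g in list(baseline_game(0.7), scaled_game(k = 0.3),
                 scaled_game(k = 0.8), crossing_game(cost = 0.05))) {
    co <- cooperative_optimum(g)
    opt <- optimize(function(q) symmetric_payoff(q, g), c(0, 1),
                    maximum = TRUE, tol = 1e-10)
    expect_equal(co$payoff, symmetric_payoff(co$q, g))
    expect_gte(co$payoff, opt$objective - 1e-9)
  }
})

test_that("dilemma classifier: baseline is a tragedy, residual efficacy is not", {
  rep1 <- classify_dilemma(baseline_game(0.5))
  expect_true(rep1$is_tragedy)
  expect_equal(rep1$dominant_strategy, 1)
  expect_equal(rep1$equilibrium_q, 1)
  expect_equal(rep1$equilibrium_payoff, -0.5)
  expect_equal(rep1$cooperative_payoff, -0.375)
  rep2 <- classify_dilemma(residual_game(0.5, 0.2))
  expect_false(rep2$is_tragedy)
  expect_equal(rep2$equilibrium_q, rep2$cooperative_q)
  # payoffs scale with phi; the strict ordering survives any phi > 0
  rep3 <- classify_dilemma(baseline_game(1e-9))
  expect_true(rep3$is_tragedy)
  # argmax property: cooperation is never worse than equilibrium
  for (g in list(baseline_game(0.2), residual_game(0.8, 0.3),
                 crossing_game(), scaled_game())) {
    r <- classify_dilemma(g)
    expect_gte(r$cooperative_payoff, r$equilibrium_payoff - 1e-12)
  }
})

test_that("crossing-point solver finds the smallest interior meeting", {
  g <- baseline_game(0.5)
  curves <- function(g) list(
    T = function(q) pure_payoffs(q, g)$payoff_T,
    U = function(q) pure_payoffs(q, g)$payoff_U)
  cb <- curves(g)
  # baseline curves meet only at the q = 1 boundary
  expect_null(crossing_point(cb$T, cb$U))
  # tangency at q' when there are no side effects
  c0 <- curves(crossing_game(q_prime = 0.5, cost = 0))
  cp0 <- crossing_point(c0$T, c0$U)
  expect_equal(cp0$q, 0.5, tolerance = 1e-8)
  expect_false(cp0$t_strictly_below)
  # genuine crossing at q' (1 - c/phi) with side effects
  c1 <- curves(crossing_game(q_prime = 0.5, cost = 0.05, phi = 0.5))
  cp1 <- crossing_point(c1$T, c1$U)
  expect_equal(cp1$q, 0.45, tolerance = 1e-8)
  expect_true(cp1$t_strictly_below)
  expect_error(crossing_point(function(q) -q, function(q) -q),
               "degenerate")
})

test_that("strict Nash implies resistance to invasion on random affine games", {
  set.seed(42)
  checked <- 0L
  while (checked < 100L) {
    gm <- rand_affine_game()
    payoff <- function(p, q) p * gm$piT(q) + (1 - p) * gm$piU(q)
    for (p_star in c(0, 1)) {
      gap <- (2 * p_star - 1) * (gm$piT(p_star) - gm$piU(p_star))
      if (gap > 1e-6) {  # strict symmetric Nash equilibrium
        res <- abxgame:::ess_conditions(
          p_star, gm$piT, gm$piU,
          mutants = seq(0, 1, length.out = 21),
          epsilons = 10^(-6:-1))
        expect_true(res$nash_ok)
        expect_true(res$strict)
        # invasion resisted at least for sufficiently small fractions
        expect_gt(res$barrier_estimate, 0)
        checked <- checked + 1L
      }
    }
  }
})

test_that("a tight Nash condition plus the second condition implies invasion resistance", {
  set.seed(43)
  for (rep in 1:100) {
    # payoff gap beta * (1 - q): ties exactly at the all-treat state
    beta <- runif(1, 0.1, 2)
    base <- runif(2, -1, 1)
    piU <- function(q) base[1] + base[2] * q
    piT <- function(q) piU(q) + beta * (1 - q)
    res <- abxgame:::ess_conditions(1, piT, piU,
                                    mutants = seq(0, 1, length.out = 21),
                                    epsilons = 10^(-6:-1))
    expect_true(res$nash_ok)
    expect_false(res$strict)
    expect_true(res$second_condition_ok)
    expect_true(res$invasion_ok)
  }
})

test_that("invasion resistance on a shrinking ladder implies the Nash condition", {
  set.seed(44)
  found <- 0L
  for (rep in 1:300) {
    gm <- rand_affine_game()
    for (p_star in c(0, 1)) {
      res <- abxgame:::ess_conditions(
        p_star, gm$piT, gm$piU,
        mutants = seq(0, 1, length.out = 21),
        epsilons = c(1e-6, 1e-5, 1e-4))
      if (res$invasion_ok) {
        expect_true(res$nash_ok)
        found <- found + 1L
      }
    }
  }
  expect_gt(found, 20L)  # the implication was actually exercised
})
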