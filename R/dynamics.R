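#' Replicator right-hand side (baseline game)
#'
#' The replicator equation for the baseline prescribing game is
#' `dq/dt = phi * q * (1 - q)^2`: the frequency of the treat strategy grows
#' in proportion to its payoff advantage over the population average. The
#' velocity is nonnegative everywhere and vanishes only at the rest points
#' `q = 0`, `q = 1` (or when `phi = 0`); the infection probability `phi`
#' purely rescales time.
#'
#' @param q treated fraction(s) in `[0, 1]`.
#' @param phi infection probability in `[0, 1]`.
#' @return Velocity `dq/dt`, vectorized over `q` and `phi`.
#' @examples
#' replicator_rhs(1/3, 1)  # global maximum 4/27
#' @export
replicator_rhs <- function(q, phi) {
  check_q(q)
  if (!is.numeric(phi) || any(!is.finite(phi)) || any(phi < 0) ||
      any(phi > 1))
    stop("`phi` must lie in [0, 1]", call. = FALSE)
  phi * q * (1 - q)^2
}

#' Replicator velocity for any game variant
#'
#' General form `q * (1 - q) * (payoff_T(q) - payoff_U(q))` built from the
#' game's own pure-strategy payoffs; reduces exactly to [replicator_rhs()]
#' for the baseline variant.
#'
#' @inheritParams relative_risk
#' @return Velocity `dq/dt`, vectorized over `q`.
#' @export
replicator_velocity <- function(q, params) {
  params <- as_game(params)
  pp <- pure_payoffs(q, params)
  q * (1 - q) * (pp$payoff_T - pp$payoff_U)
}

#' Average population payoff
#'
#' Mean payoff when a fraction `q` plays T and `1 - q` plays U:
#' `q * payoff_T + (1 - q) * payoff_U`, i.e. `phi * (-q^2 + q - 1)` for the
#' baseline game. Identical to [symmetric_payoff()]; exposed under the name
#' used in the replicator derivation.
#'
#' @inheritParams relative_risk
#' @return Normalized mean utility, vectorized over `q`.
#' @export
average_payoff <- function(q, params) {
  symmetric_payoff(q, params)
}

#' Replicator velocity derived from payoff curves
#'
#' Implements the defining form of the replicator dynamic: the current
#' frequency of T times the payoff of T relative to the population average,
#' `q * (payoff_T(q) - avg(q))` with
#' `avg(q) = q * payoff_T(q) + (1 - q) * payoff_U(q)`. Algebraically equal
#' to `q * (1 - q) * (payoff_T(q) - payoff_U(q))`, and with the baseline
#' pure payoffs it reduces exactly to `phi * q * (1 - q)^2`.
#'
#' @param q treated fraction(s).
#' @param payoff_T_curve,payoff_U_curve functions of `q` (vectorized).
#' @return Velocity `dq/dt`.
#' @export
replicator_from_payoffs <- function(q, payoff_T_curve, payoff_U_curve) {
  check_q(q)
  piT <- payoff_T_curve(q)
  piU <- payoff_U_curve(q)
  q * (piT - (q * piT + (1 - q) * piU))
}

#' First integral of the baseline replicator flow
#'
#' The baseline equation is separable; partial fractions give the conserved
#' quantity `log(q / (1 - q)) + 1 / (1 - q) - phi * t`, constant along any
#' interior trajectory. Used as an independent oracle for the numerical
#' integrator.
#'
#' @param q state(s) strictly inside (0, 1).
#' @param t time(s).
#' @param phi infection probability.
#' @return The invariant value(s).
#' @export
first_integral <- function(q, t, phi) {
  if (any(q <= 0) || any(q >= 1))
    stop("the first integral is defined for q strictly inside (0, 1)",
         call. = FALSE)
  log(q / (1 - q)) + 1 / (1 - q) - phi * t
}

# minimal fixed-step RK4, used as a second-opinion integrator in tests
rk4_integrate <- function(rhs, q0, times) {
  n <- length(times)
  q <- numeric(n)
  q[1] <- q0
  for (i in seq_len(n - 1L)) {
    h <- times[i + 1L] - times[i]
    y <- q[i]
    k1 <- rhs(y)
    k2 <- rhs(min(1, max(0, y + h / 2 * k1)))
    k3 <- rhs(min(1, max(0, y + h / 2 * k2)))
    k4 <- rhs(min(1, max(0, y + h * k3)))
    q[i + 1L] <- min(1, max(0, y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)))
  }
  q
}

#' Integrate the replicator dynamics
#'
#' Numerically integrates the replicator equation from `q0` up to `t_max`
#' on a logarithmically spaced time grid, using an adaptive solver
#' (`deSolve::ode`, lsoda) with tight tolerances; the state is clamped to
#' `[0, 1]` after each output step. The trajectory is flagged converged
#' when the terminal velocity is below `1e-10` and the terminal state is
#' within `1e-6` of a rest point. For any interior start with `phi > 0`
#' the flow is monotone toward the all-treat state `q = 1`; note the
#' approach is algebraic (like `1/(phi t)`), so reaching `|q - 1| < 1e-6`
#' requires `t_max` of order `1e6 / phi` or more.
#'
#' @param q0 initial treated fraction in `[0, 1]`.
#' @param phi infection probability (ignored when `params` is given, which
#'   then supplies both the variant and its `phi`).
#' @param t_max integration horizon in dimensionless model time.
#' @param params optional `abx_game` for non-baseline variants.
#' @param rtol,atol solver tolerances.
#' @param n_out number of output points (log-spaced).
#' @param method `"lsoda"` (adaptive, default) or `"rk4"` (fixed-step
#'   second opinion).
#' @return An object of class `replicator_trajectory`: list with `times`,
#'   `states`, `phi`, `converged`, `terminal_q`, `method`.
#' @examples
#' tr <- integrate_replicator(0.1, phi = 0.5, t_max = 1e4)
#' tr$terminal_q
#' @export
integrate_replicator <- function(q0, phi = NULL, t_max = 1e4, params = NULL,
                                 rtol = 1e-9, atol = 1e-9, n_out = 400L,
                                 method = c("lsoda", "rk4")) {
  method <- match.arg(method)
  if (!is.null(params)) {
    params <- as_game(params)
    phi <- params$phi
    rhs <- function(q) replicator_velocity(min(1, max(0, q)), params)
  } else {
    if (is.null(phi)) stop("supply `phi` or `params`", call. = FALSE)
    if (phi < 0 || phi > 1) stop("`phi` must lie in [0, 1]", call. = FALSE)
    rhs <- function(q) replicator_rhs(min(1, max(0, q)), phi)
  }
  check_q(q0)
  if (!is.numeric(t_max) || t_max <= 0)
    stop("`t_max` must be > 0", call. = FALSE)

  times <- unique(c(0, 10^seq(log10(t_max) - 8, log10(t_max),
                              length.out = n_out)))
  states <- if (method == "rk4") {
    # log-spaced grid is too coarse for fixed steps; refine uniformly
    ft <- seq(0, t_max, length.out = max(20000L, n_out))
    q_all <- rk4_integrate(rhs, q0, ft)
    vapply(times, function(t) q_all[which.min(abs(ft - t))], numeric(1))
  } else {
    sol <- deSolve::ode(y = c(q = q0), times = times,
                        func = function(t, y, parms)
                          list(rhs(as.numeric(y))),
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 1e5)
    if (any(!is.finite(sol[, "q"])))
      stop("integration produced non-finite states (q0 = ", q0,
           ", phi = ", phi, ")", call. = FALSE)
    pmin(1, pmax(0, as.numeric(sol[, "q"])))
  }

  terminal_q <- states[length(states)]
  rest <- if (is.null(params)) c(0, 1) else c(0, 1, interior_ties(params))
  converged <- abs(rhs(terminal_q)) < 1e-10 &&
    min(abs(terminal_q - rest)) < 1e-6
  structure(
    list(times = times, states = states, phi = phi, converged = converged,
         terminal_q = terminal_q, method = method),
    class = "replicator_trajectory")
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  cat(sprintf(
    "Replicator trajectory: phi = %g, q(0) = %g -> q(%g) = %.8f%s\n",
    x$phi, x$states[1], x$times[length(x$times)], x$terminal_q,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
plot.replicator_trajectory <- function(x, ...) {
  plot(x$times, x$states, type = "l", log = "x",
       xlab = "time (dimensionless)", ylab = "treated fraction q",
       ylim = c(0, 1), ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Classify a rest point of the replicator flow
#'
#' Evaluates the derivative of the velocity at the rest point
#' (analytically `phi * (1 - q) * (1 - 3q)` for the baseline game, by
#' central difference otherwise): a positive derivative means the flow
#' pulls away (unstable), a negative one that it pulls in (stable
#' attractor). Where the linearization is uninformative (derivative zero,
#' as at the baseline's `q = 1`) one-sided sign probes at `q_star +- h`
#' decide: flow toward the point from every occupied side means a
#' degenerate attractor.
#'
#' @param q_star rest-point location in `[0, 1]`.
#' @param phi infection probability > 0 (ignored when `params` given).
#' @param params optional `abx_game` for non-baseline variants.
#' @param h probe/differencing step.
#' @param tol velocity tolerance for accepting `q_star` as a rest point.
#' @return List with `q_star`, `derivative`, and `classification` (one of
#'   `"STABLE_ATTRACTOR"`, `"UNSTABLE"`, `"DEGENERATE_ATTRACTING"`,
#'   `"DEGENERATE_REPELLING"`).
#' @examples
#' classify_rest_point(0, phi = 0.5)$classification  # UNSTABLE
#' classify_rest_point(1, phi = 0.5)$classification  # DEGENERATE_ATTRACTING
#' @export
classify_rest_point <- function(q_star, phi = NULL, params = NULL,
                                h = 1e-6, tol = 1e-8) {
  baseline <- is.null(params)
  if (!baseline) {
    params <- as_game(params)
    phi <- params$phi
    rhs <- function(q) replicator_velocity(q, params)
  } else {
    rhs <- function(q) replicator_rhs(q, phi)
  }
  check_q(q_star)
  v <- rhs(q_star)
  if (abs(v) > tol)
    stop("q_star = ", q_star, " is not a rest point (|velocity| = ",
         format(abs(v)), ")", call. = FALSE)

  deriv <- if (baseline || params$variant == "baseline") {
    phi * (1 - q_star) * (1 - 3 * q_star)
  } else {
    # product rule on q (1-q) gap(q): exact in the boundary factors, so
    # only the smooth payoff gap is differenced numerically
    gap <- function(q) {
      pp <- pure_payoffs(q, params)
      pp$payoff_T - pp$payoff_U
    }
    lo <- max(0, q_star - h)
    hi <- min(1, q_star + h)
    dgap <- (gap(hi) - gap(lo)) / (hi - lo)
    (1 - 2 * q_star) * gap(q_star) + q_star * (1 - q_star) * dgap
  }

  dtol <- 1e-8
  classification <- if (deriv > dtol) "UNSTABLE"
  else if (deriv < -dtol) "STABLE_ATTRACTOR"
  else {
    attracting <- TRUE
    if (q_star > 0) attracting <- attracting && rhs(q_star - h) > 0
    if (q_star < 1) attracting <- attracting && rhs(q_star + h) < 0
    if (attracting) "DEGENERATE_ATTRACTING" else "DEGENERATE_REPELLING"
  }
  list(q_star = q_star, derivative = deriv, classification = classification)
}

#' Rest points of the replicator dynamics
#'
#' For `phi > 0` the baseline flow has exactly two rest points, `q = 0`
#' (unstable) and `q = 1` (attracting); game variants whose payoff curves
#' tie at an interior state contribute an additional interior rest point
#' there. For `phi = 0` every state is at rest and the whole interval is
#' flagged instead.
#'
#' @param phi infection probability >= 0 (ignored when `params` given).
#' @param params optional `abx_game`.
#' @param h probe step passed to [classify_rest_point()].
#' @return List with `whole_interval` (logical; `TRUE` only when
#'   `phi = 0`) and `points`, a data frame with columns `q_star`,
#'   `derivative`, `classification`.
#' @examples
#' find_rest_points(0.5)$points
#' @export
find_rest_points <- function(phi = NULL, params = NULL, h = 1e-6) {
  if (!is.null(params)) {
    params <- as_game(params)
    phi <- params$phi
  }
  if (is.null(phi) || phi < 0)
    stop("`phi` must be >= 0", call. = FALSE)
  if (phi == 0)
    return(list(whole_interval = TRUE,
                points = data.frame(q_star = numeric(0),
                                    derivative = numeric(0),
                                    classification = character(0))))
  qs <- c(0, if (!is.null(params)) interior_ties(params), 1)
  rows <- lapply(qs, function(q)
    as.data.frame(classify_rest_point(q, phi = phi, params = params, h = h)))
  list(whole_interval = FALSE, points = do.call(rbind, rows))
}

#' Replicator vector field over a (phi, q) grid
#'
#' Evaluates the velocity on the product grid, the data behind the
#' three-dimensional phase portrait: zero along the edges `q = 0` and
#' `q = 1`, increasing in `phi` at fixed interior `q`, and peaked at
#' `q = 1/3` for fixed `phi`.
#'
#' @param phi_grid,q_grid grids within `[0, 1]`.
#' @param params optional `abx_game`; its variant is re-parameterized at
#'   each `phi` of the grid (the variant constants are kept).
#' @return Data frame with columns `phi`, `q`, `qdot`.
#' @export
vector_field <- function(phi_grid = seq(0, 1, length.out = 101),
                         q_grid = seq(0, 1, length.out = 101),
                         params = NULL) {
  check_q(q_grid)
  if (any(phi_grid < 0) || any(phi_grid > 1))
    stop("`phi_grid` must lie within [0, 1]", call. = FALSE)
  grid <- expand.grid(q = q_grid, phi = phi_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("phi", "q")]
  grid$qdot <- if (is.null(params)) {
    replicator_rhs(grid$q, grid$phi)
  } else {
    params <- as_game(params)
    vapply(seq_len(nrow(grid)), function(i) {
      p_i <- prescribing_game(phi = max(grid$phi[i], 1e-12), n = params$n,
                              r_U = params$r_U, variant = params$variant,
                              k = params$k, lambda = params$lambda,
                              q_prime = params$q_prime,
                              side_effect_cost = params$side_effect_cost)
      grid$phi[i] / max(grid$phi[i], 1e-12) *
        replicator_velocity(grid$q[i], p_i)
    }, numeric(1))
  }
  grid
}

#' Peak velocity of the replicator flow
#'
#' The baseline velocity `phi * q * (1 - q)^2` is maximized over `q` at the
#' root of its derivative in (0, 1), `q = 1/3`, independently of `phi`; the
#' infection probability only scales the peak height `4 * phi / 27`.
#' Prescribing therefore spreads fastest when a third of patients are
#' treated, and faster the likelier a true bacterial infection.
#'
#' @param phi infection probability > 0.
#' @return List with `q_at_max` and `qdot_max`.
#' @examples
#' peak_velocity(1)  # q = 1/3, velocity 4/27
#' @export
peak_velocity <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi > 1)
    stop("`phi` must be a single value in (0, 1]; the argmax is undefined ",
         "at phi = 0 (every state is at rest)", call. = FALSE)
  # d/dq [q (1-q)^2] = (1-q)(1-3q): interior root q = 1/3
  q_at_max <- 1 / 3
  list(q_at_max = q_at_max, qdot_max = replicator_rhs(q_at_max, phi))
}
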