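#' Best response to a population state
#'
#' Because the expected payoff is affine in the prescribing probability `p`
#' at fixed `q`, the best response is `p = 1` when the pure-T payoff
#' exceeds the pure-U payoff, `p = 0` when it is below, and the whole
#' interval `[0, 1]` when the two tie (as happens at `q = 1` in the
#' baseline model, where resistance has equalized treated and untreated
#' risks).
#'
#' @inheritParams relative_risk
#' @param tol payoff-equality tolerance (normalized units).
#' @return A list with `type` (`"point"` or `"interval"`) and `p` (a single
#'   strategy, or the interval endpoints `c(0, 1)`).
#' @examples
#' best_response(0.5, prescribing_game(phi = 0.5))  # treat: p = 1
#' best_response(1,   prescribing_game(phi = 0.5))  # tie: [0, 1]
#' @export
best_response <- function(q, params, tol = 1e-12) {
  params <- as_game(params)
  check_q(q)
  if (length(q) != 1L) stop("`q` must be a single state", call. = FALSE)
  pp <- pure_payoffs(q, params)
  gap <- pp$payoff_T - pp$payoff_U
  if (gap > tol)       list(type = "point", p = 1)
  else if (gap < -tol) list(type = "point", p = 0)
  else                 list(type = "interval", p = c(0, 1))
}

#' Is a strategy dominant?
#'
#' A strategy is dominant when it earns at least as much as every
#' alternative at every population state. The payoff is affine in `p`, so
#' dominance against the pure strategies suffices; the check is still run
#' over an explicit `q` grid, which serves as the oracle for the analytic
#' shortcut.
#'
#' @param p the candidate strategy.
#' @param params an `abx_game`.
#' @param q_grid states at which to test; must cover `[0, 1]`.
#' @param tol payoff-equality tolerance.
#' @return List with logicals `dominant` (weak dominance everywhere),
#'   `strict` (strict on the interior of the grid) and `strict_everywhere`
#'   (strict at the boundary states too).
#' @examples
#' is_dominant(1, prescribing_game(phi = 0.5))$dominant  # TRUE
#' @export
is_dominant <- function(p, params, q_grid = seq(0, 1, length.out = 1001),
                        tol = 1e-12) {
  params <- as_game(params)
  check_p(p)
  if (length(q_grid) == 0L) stop("`q_grid` must be nonempty", call. = FALSE)
  check_q(q_grid)
  pp <- pure_payoffs(q_grid, params)
  own <- p * pp$payoff_T + (1 - p) * pp$payoff_U
  # affine in p: the best alternative payoff is the better pure strategy
  best_alt <- pmax(pp$payoff_T, pp$payoff_U)
  margin <- own - best_alt
  interior <- q_grid > 0 & q_grid < 1
  list(dominant = all(margin >= -tol),
       strict = all(margin >= -tol) &&
         all(own[interior] > pmin(pp$payoff_T, pp$payoff_U)[interior] + tol),
       strict_everywhere = all(own > pmin(pp$payoff_T, pp$payoff_U) + tol))
}

#' Locate the crossing point of two payoff curves
#'
#' Returns the smallest `q` in the open interval (0, 1) at which the two
#' curves are equal, found by a sign-change scan refined by bisection
#' (`stats::uniroot`) to the requested tolerance. Boundary-only meetings
#' (e.g. the baseline curves, which meet at `q = 1` exactly) yield no
#' interior crossing.
#'
#' @param payoff_T_curve,payoff_U_curve functions of `q` on `[0, 1]`
#'   (vectorized), e.g. built from [pure_payoffs()].
#' @param tol root tolerance.
#' @param grid_n scan resolution.
#' @return `NULL` if the curves never meet on (0, 1); otherwise a list with
#'   `q` (the smallest interior meeting point) and `t_strictly_below`
#'   (`TRUE` when the T curve falls strictly below the U curve somewhere,
#'   i.e. a genuine crossing rather than a tangency).
#' @export
crossing_point <- function(payoff_T_curve, payoff_U_curve, tol = 1e-10,
                           grid_n = 4001L) {
  qs <- seq(0, 1, length.out = grid_n)
  d <- function(q) payoff_T_curve(q) - payoff_U_curve(q)
  ds <- d(qs)
  if (all(abs(ds) <= tol))
    stop("payoff curves coincide everywhere; crossing point is degenerate",
         call. = FALSE)
  root <- NULL
  for (i in seq_len(grid_n - 1L)) {
    lo <- ds[i]; hi <- ds[i + 1L]
    if (abs(lo) <= tol && abs(hi) <= tol) next  # plateau of ties
    if (lo * hi <= 0) {
      r <- if (abs(lo) <= tol) qs[i]
           else if (abs(hi) <= tol) qs[i + 1L]
           else uniroot(d, c(qs[i], qs[i + 1L]), tol = tol)$root
      if (r > tol && r < 1 - tol) { root <- r; break }
    }
  }
  if (is.null(root)) return(NULL)
  list(q = root, t_strictly_below = any(ds < -tol))
}

# interior roots of payoff_T - payoff_U for a parameterized game
interior_ties <- function(params, tol = 1e-10) {
  cp <- tryCatch(
    crossing_point(function(q) pure_payoffs(q, params)$payoff_T,
                   function(q) pure_payoffs(q, params)$payoff_U,
                   tol = tol),
    error = function(e) NULL)
  if (is.null(cp)) numeric(0) else cp$q
}

#' Symmetric Nash equilibria
#'
#' Solves the best-response fixed point on symmetric profiles: every doctor
#' plays `p`, so the population state is `q = p`, and `p*` is an
#' equilibrium when `p*` is a best response to `q = p*`. Candidates are the
#' boundary strategies and any interior payoff-tie point. Strictness at a
#' boundary equilibrium where the payoffs tie exactly (baseline `p* = 1`)
#' is reported as the limit of strict best responses: the flag is `TRUE`
#' when the strategy is the unique best response at every interior resident
#' state.
#'
#' @param params an `abx_game`.
#' @param tol payoff-equality tolerance.
#' @return A data frame with columns `p_star`, `strict`, and `type`
#'   (`"boundary"` or `"interior"`).
#' @examples
#' find_symmetric_nash(prescribing_game(phi = 0.5))  # p* = 1, strict
#' @export
find_symmetric_nash <- function(params, tol = 1e-12) {
  params <- as_game(params)
  d <- function(q) {
    pp <- pure_payoffs(q, params)
    pp$payoff_T - pp$payoff_U
  }
  interior_grid <- seq(1e-6, 1 - 1e-6, length.out = 1001)
  d_int <- d(interior_grid)

  out <- list()
  if (d(1) >= -tol)   # T weakly best against all-T
    out[[length(out) + 1L]] <- data.frame(
      p_star = 1, strict = d(1) > tol || all(d_int > tol),
      type = "boundary")
  if (d(0) <= tol)    # U weakly best against all-U
    out[[length(out) + 1L]] <- data.frame(
      p_star = 0, strict = d(0) < -tol || all(d_int < -tol),
      type = "boundary")
  for (r in interior_ties(params))
    out[[length(out) + 1L]] <- data.frame(
      p_star = r, strict = FALSE, type = "interior")

  if (length(out) == 0L)
    return(data.frame(p_star = numeric(0), strict = logical(0),
                      type = character(0)))
  res <- do.call(rbind, out)
  res[!duplicated(round(res$p_star, 10)), , drop = FALSE]
}

#' Cooperative optimum of the symmetric payoff
#'
#' Maximizes [symmetric_payoff()] over `q` in `[0, 1]`: the best payoff
#' every doctor could secure if all adopted the same prescribing rate. The
#' quadratic variants are solved in closed form (vertex clamped to the unit
#' interval); the piecewise crossing variant by comparing its breakpoints
#' and clamped vertex.
#'
#' @param params an `abx_game`.
#' @return List with `q` (the argmax) and `payoff` (the maximum).
#' @examples
#' cooperative_optimum(prescribing_game(phi = 0.5))  # q = 1/2
#' @export
cooperative_optimum <- function(params) {
  params <- as_game(params)
  phi <- params$phi
  q_star <- switch(params$variant,
    # phi*(-q^2 + q - 1): vertex 1/2
    baseline = 0.5,
    # phi*(-k q^2 + q - 1): vertex 1/(2k), clamped
    scaled_k = min(1, 1 / (2 * params$k)),
    # -lambda q^2 + phi q - phi: vertex phi/(2 lambda), clamped;
    # lambda < phi/2 pushes the vertex past 1, so the argmax is q = 1
    residual_lambda = min(1, phi / (2 * params$lambda)),
    crossing = {
      qp <- params$q_prime; cc <- params$side_effect_cost
      # on [0, q']: -(phi/q') q^2 + (phi - c) q - phi; beyond q' the
      # payoff -phi - c q only falls
      vertex <- max(0, min(qp, (phi - cc) * qp / (2 * phi)))
      cand <- c(0, vertex, qp, 1)
      cand[which.max(symmetric_payoff(cand, params))]
    })
  list(q = q_star, payoff = symmetric_payoff(q_star, params))
}

#' Classify the game as a tragedy of the commons (or not)
#'
#' A tragedy of the commons arises when the individually rational
#' (dominant) strategy drives the population to an equilibrium whose payoff
#' is strictly worse for everyone than an attainable cooperative outcome.
#' The baseline game is a tragedy: T is dominant, the equilibrium payoff at
#' `q = 1` is `-phi`, yet all doctors prescribing at rate 1/2 would earn
#' `-3*phi/4`. Under residual efficacy with `lambda < phi/2` the
#' equilibrium coincides with the cooperative optimum and the dilemma
#' disappears.
#'
#' @param params an `abx_game`.
#' @param tol strict-inequality tolerance.
#' @return An object of class `dilemma_report`: a list with
#'   `dominant_strategy` (1, 0 or `NA`), `equilibrium_q`,
#'   `equilibrium_payoff`, `cooperative_q`, `cooperative_payoff`,
#'   `is_tragedy`.
#' @examples
#' classify_dilemma(prescribing_game(phi = 0.5))$is_tragedy  # TRUE
#' @export
classify_dilemma <- function(params, tol = 1e-12) {
  params <- as_game(params)
  dom <- if (is_dominant(1, params)$dominant) 1
         else if (is_dominant(0, params)$dominant) 0
         else NA_real_
  nash <- find_symmetric_nash(params)
  eq_q <- if (!is.na(dom) && any(abs(nash$p_star - dom) < 1e-9)) dom
          else if (nrow(nash) > 0L) nash$p_star[[1L]]
          else NA_real_
  eq_pay <- if (is.na(eq_q)) NA_real_ else symmetric_payoff(eq_q, params)
  coop <- cooperative_optimum(params)
  structure(
    list(dominant_strategy = dom,
         equilibrium_q = eq_q,
         equilibrium_payoff = eq_pay,
         cooperative_q = coop$q,
         cooperative_payoff = coop$payoff,
         is_tragedy = !is.na(dom) && !is.na(eq_pay) &&
           isTRUE(abs(eq_q - dom) < 1e-9) &&
           eq_pay < coop$payoff - tol),
    class = "dilemma_report")
}

#' @export
print.dilemma_report <- function(x, ...) {
  cat("Dilemma classification\n")
  cat("  dominant strategy:",
      if (is.na(x$dominant_strategy)) "none"
      else if (x$dominant_strategy == 1) "T (p = 1)" else "U (p = 0)", "\n")
  cat(sprintf("  equilibrium:  q = %g, payoff = %g\n",
              x$equilibrium_q, x$equilibrium_payoff))
  cat(sprintf("  cooperative:  q = %g, payoff = %g\n",
              x$cooperative_q, x$cooperative_payoff))
  cat("  tragedy of the commons:", if (x$is_tragedy) "YES" else "no", "\n")
  invisible(x)
}
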