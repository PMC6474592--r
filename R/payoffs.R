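#' Relative morbidity risk of treated patients
#'
#' The morbidity risk of antibiotic-treated patients divided by that of
#' untreated patients, as a function of the treated fraction `q`. Resistance
#' is driven by prescribing, so the risk grows with `q`: linearly from 0 to
#' 1 in the baseline model, with variant-specific shapes otherwise (see
#' [game_variants]).
#'
#' @param q treated fraction(s) in `[0, 1]`.
#' @param params an `abx_game` from [prescribing_game()].
#' @return Relative risk r_q in `[0, 1]`, vectorized over `q`.
#' @examples
#' relative_risk(c(0, 0.5, 1), prescribing_game(phi = 0.5))
#' @export
relative_risk <- function(q, params) {
  params <- as_game(params)
  check_q(q)
  switch(params$variant,
    baseline = q,
    scaled_k = params$k * q,
    # chosen so that phi * r_q = lambda * q, i.e. the pure-T payoff is
    # exactly -lambda*q
    residual_lambda = (params$lambda / params$phi) * q,
    crossing = pmin(q / params$q_prime, 1))
}

#' Pure-strategy payoffs at a population state
#'
#' Normalized payoffs of the two pure strategies at treated fraction `q`:
#' `payoff_T = -phi * r_q` (minus any side-effect cost in the crossing
#' variant) and `payoff_U = -phi`, which is independent of `q`. Payoffs are
#' expected morbidity disutilities divided by `r_U`, hence nonpositive.
#'
#' @inheritParams relative_risk
#' @return A list with numeric fields `payoff_T` and `payoff_U`, each
#'   vectorized over `q`.
#' @examples
#' pure_payoffs(c(0, 1), prescribing_game(phi = 0.5))
#' @export
pure_payoffs <- function(q, params) {
  params <- as_game(params)
  check_q(q)
  list(payoff_T = -params$phi * relative_risk(q, params) -
         params$side_effect_cost,
       payoff_U = rep(-params$phi, length(q)))
}

#' Expected payoff of a mixed strategy (normalized)
#'
#' A doctor prescribing with probability `p` while the treated fraction is
#' `q` earns `p * payoff_T(q) + (1 - p) * payoff_U(q)`; for the baseline
#' model this is `phi * (p * (1 - q) - 1)`. Affine in `p` at fixed `q`.
#'
#' @param p prescribing probability(ies) in `[0, 1]`.
#' @inheritParams relative_risk
#' @return Normalized expected utility, vectorized over `p` and `q`
#'   (recycled).
#' @examples
#' payoff_mixed(1, 1, prescribing_game(phi = 0.5))  # -phi
#' @export
payoff_mixed <- function(p, q, params) {
  params <- as_game(params)
  check_p(p)
  pp <- pure_payoffs(q, params)
  p * pp$payoff_T + (1 - p) * pp$payoff_U
}

#' Expected payoff of a mixed strategy (unnormalized)
#'
#' The raw form `p * (-r^T_q * phi) + (1 - p) * (-r_U * phi)` with
#' `r^T_q = r_q * r_U`. Dividing by `r_U` recovers [payoff_mixed()]; the
#' division is payoff-irrelevant because utilities live on an interval
#' scale.
#'
#' @inheritParams payoff_mixed
#' @return Unnormalized expected utility.
#' @export
payoff_raw <- function(p, q, params) {
  params <- as_game(params)
  params$r_U * payoff_mixed(p, q, params)
}

#' Symmetric (average) population payoff
#'
#' The payoff to each doctor when every doctor plays `p = q`, equal to the
#' population-average payoff `q * payoff_T + (1 - q) * payoff_U`. Baseline:
#' `phi * (q * (1 - q) - 1)`, a downward parabola maximized at `q = 1/2`.
#'
#' @inheritParams relative_risk
#' @return Normalized utility, vectorized over `q`.
#' @export
symmetric_payoff <- function(q, params) {
  params <- as_game(params)
  pp <- pure_payoffs(q, params)
  q * pp$payoff_T + (1 - q) * pp$payoff_U
}

#' Payoff to one player in a strategy profile
#'
#' The treated fraction implied by the profile is the mean strategy over
#' all `n` doctors ([profile_state()]); player `i` then earns
#' [payoff_mixed()] of their own strategy at that state.
#'
#' @param i player index in `1:n`.
#' @param profile numeric vector of `n` prescribing probabilities.
#' @param params an `abx_game`.
#' @return Normalized utility of player `i`.
#' @examples
#' g <- prescribing_game(phi = 1, n = 2)
#' profile_payoff(1, c(1, 0), g)  # q = 0.5, payoff phi*(1*(1-0.5)-1)
#' @export
profile_payoff <- function(i, profile, params) {
  params <- as_game(params)
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > params$n ||
      i != as.integer(i))
    stop("player index `i` must be an integer in 1..n = ", params$n,
         call. = FALSE)
  q <- profile_state(profile, params)
  payoff_mixed(profile[[i]], q, params)
}
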