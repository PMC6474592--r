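#' Model variants
#'
#' The shape of the relative morbidity risk r_q (risk of treated patients
#' divided by risk of untreated patients) distinguishes the variants:
#'
#' * `"baseline"` — r_q = q: resistance grows linearly with the treated
#'   fraction and antibiotics are useless at q = 1.
#' * `"scaled_k"` — r_q = k q with 0 < k < 1: resistance never fully
#'   destroys efficacy.
#' * `"residual_lambda"` — r_q = (lambda/phi) q, so the pure-T payoff is
#'   -lambda q with 0 < lambda < phi: antibiotics retain residual efficacy
#'   even at q = 1.
#' * `"crossing"` — efficacy is exhausted at q' < 1: r_q = min(q/q', 1),
#'   optionally with a side-effect cost that pushes the T payoff strictly
#'   below the U payoff beyond the crossing point.
#'
#' @name game_variants
#' @keywords internal
NULL

GAME_VARIANTS <- c("baseline", "scaled_k", "residual_lambda", "crossing")

#' Construct the antibiotic prescribing game
#'
#' Bundles and validates every constant of the game: the probability `phi`
#' that a symptomatic patient actually has a bacterial infection, the number
#' of prescribing doctors `n`, the baseline morbidity risk `r_U` of
#' untreated patients, and the variant-specific constants (see
#' [game_variants]).
#'
#' Payoffs are utilities on an interval scale, so all reported payoffs are
#' normalized by division through `r_U` (hence lie in `[-phi, 0]` for the
#' baseline model); [payoff_raw()] recovers the unnormalized form.
#'
#' @param phi probability in (0, 1] that a symptomatic patient has a
#'   bacterial infection.
#' @param n integer >= 2, number of prescribing doctors. Only the
#'   strategy-profile to population-state mapping uses it.
#' @param r_U baseline morbidity risk of untreated patients, > 0.
#' @param variant one of `"baseline"`, `"scaled_k"`, `"residual_lambda"`,
#'   `"crossing"`.
#' @param k resistance-scaling constant in (0, 1); `scaled_k` only.
#' @param lambda residual-efficacy slope in (0, phi); `residual_lambda`
#'   only.
#' @param q_prime efficacy-exhaustion point in (0, 1); `crossing` only.
#' @param side_effect_cost nonnegative extra disutility (normalized units)
#'   for treated patients; `crossing` only.
#'
#' @return An object of class `abx_game`: a validated list of the above.
#' @examples
#' g <- prescribing_game(phi = 0.5)
#' pure_payoffs(0.5, g)
#' @export
prescribing_game <- function(phi = 0.5, n = 2L, r_U = 1,
                             variant = c("baseline", "scaled_k",
                                         "residual_lambda", "crossing"),
                             k = NULL, lambda = NULL, q_prime = NULL,
                             side_effect_cost = 0) {
  variant <- match.arg(variant)
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) ||
      phi <= 0 || phi > 1)
    stop("`phi` must be a single number in (0, 1]", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != as.integer(n))
    stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(r_U) || length(r_U) != 1L || !is.finite(r_U) || r_U <= 0)
    stop("`r_U` must be a single number > 0", call. = FALSE)

  if (variant == "scaled_k") {
    if (is.null(k) || !is.numeric(k) || length(k) != 1L || k <= 0 || k >= 1)
      stop("variant \"scaled_k\" requires `k` in (0, 1)", call. = FALSE)
  }
  if (variant == "residual_lambda") {
    if (is.null(lambda) || !is.numeric(lambda) || length(lambda) != 1L ||
        lambda <= 0 || lambda >= phi)
      stop("variant \"residual_lambda\" requires `lambda` in (0, phi); ",
           "got lambda = ", if (is.null(lambda)) "NULL" else lambda,
           " with phi = ", phi, call. = FALSE)
  }
  if (variant == "crossing") {
    if (is.null(q_prime) || !is.numeric(q_prime) || length(q_prime) != 1L ||
        q_prime <= 0 || q_prime >= 1)
      stop("variant \"crossing\" requires `q_prime` in (0, 1)", call. = FALSE)
    if (!is.numeric(side_effect_cost) || length(side_effect_cost) != 1L ||
        side_effect_cost < 0)
      stop("`side_effect_cost` must be >= 0", call. = FALSE)
  }

  structure(
    list(phi = phi, n = as.integer(n), r_U = r_U, variant = variant,
         k = k, lambda = lambda, q_prime = q_prime,
         side_effect_cost = if (variant == "crossing") side_effect_cost else 0),
    class = "abx_game")
}

#' @export
print.abx_game <- function(x, ...) {
  cat("Antibiotic prescribing game\n")
  cat(sprintf("  phi = %g (infection probability), n = %d doctors, r_U = %g\n",
              x$phi, x$n, x$r_U))
  cat("  variant:", x$variant)
  extra <- switch(x$variant,
    scaled_k = sprintf(" (k = %g)", x$k),
    residual_lambda = sprintf(" (lambda = %g)", x$lambda),
    crossing = sprintf(" (q' = %g, side-effect cost = %g)",
                       x$q_prime, x$side_effect_cost),
    "")
  cat(extra, "\n", sep = "")
  invisible(x)
}

as_game <- function(params) {
  if (!inherits(params, "abx_game"))
    stop("`params` must be an `abx_game` object from prescribing_game()",
         call. = FALSE)
  params
}

check_q <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("treated fraction `q` must lie in [0, 1]", call. = FALSE)
  q
}

check_p <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("strategy `p` must be a probability in [0, 1]", call. = FALSE)
  p
}

#' Map a strategy profile to the population state
#'
#' The treated fraction implied by a profile of mixed strategies is the mean
#' prescribing probability over all `n` doctors (mean-field reading: each
#' doctor treats the population state as given).
#'
#' @param profile numeric vector of `n` prescribing probabilities.
#' @param params an `abx_game`.
#' @return The treated fraction `q` in `[0, 1]`.
#' @export
profile_state <- function(profile, params) {
  params <- as_game(params)
  check_p(profile)
  if (length(profile) != params$n)
    stop("profile length (", length(profile),
         ") must equal the number of doctors n = ", params$n, call. = FALSE)
  mean(profile)
}

#' Read game parameters from a plain-text config file
#'
#' Parses `key = value` lines (`#` starts a comment). Recognized keys:
#' `phi`, `n`, `r_U`, `variant`, `k`, `lambda`, `q_prime`,
#' `side_effect_cost`. Unknown keys raise an error.
#'
#' @param path path to the config file.
#' @param ... overrides applied after the file is read (e.g. `phi = 0.8`),
#'   taking precedence over file values.
#' @return An `abx_game`.
#' @export
read_game_config <- function(path, ...) {
  vals <- parse_config_file(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(prescribing_game, vals)
}

parse_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected `key = value`): ", ln,
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    allowed <- c("phi", "n", "r_U", "variant", "k", "lambda", "q_prime",
                 "side_effect_cost")
    if (!key %in% allowed)
      stop("unknown config key: ", key, call. = FALSE)
    vals[[key]] <- if (key == "variant") val else as.numeric(val)
  }
  vals
}
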