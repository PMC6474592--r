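#' Tabulate the pure-strategy payoff curves
#'
#' Evaluates the T and U payoffs on an even grid of treated fractions —
#' the data behind the payoff-function figure. For the baseline game at
#' `phi = 0.5` the T payoff falls linearly from 0 to `-0.5` while the U
#' payoff is flat at `-0.5`.
#'
#' @param phi infection probability (used when `params` is not supplied).
#' @param q_steps number of grid rows, >= 2.
#' @param params optional `abx_game`; overrides `phi` and selects the
#'   variant.
#' @return Data frame with columns `q`, `payoff_T`, `payoff_U`.
#' @examples
#' head(payoff_table(phi = 0.5, q_steps = 5))
#' @export
payoff_table <- function(phi = 0.5, q_steps = 101L, params = NULL) {
  if (!is.numeric(q_steps) || q_steps < 2)
    stop("`q_steps` must be >= 2", call. = FALSE)
  if (is.null(params)) params <- prescribing_game(phi = phi)
  params <- as_game(params)
  q <- seq(0, 1, length.out = as.integer(q_steps))
  pp <- pure_payoffs(q, params)
  data.frame(q = q, payoff_T = pp$payoff_T, payoff_U = pp$payoff_U)
}

#' Full analysis report of a prescribing game
#'
#' Aggregates the package's analyses into one structured document: the
#' dilemma classification, the symmetric Nash set, the evolutionary
#' stability check for the equilibrium strategy, rest points of the
#' replicator flow with stability classifications, the cooperative
#' optimum, and the peak-velocity summary.
#'
#' @param params an `abx_game`.
#' @param mutant_grid,epsilon_grid grids forwarded to [check_ess()].
#' @return An object of class `abx_report` (a named list, JSON-ready).
#' @examples
#' rep <- full_report(prescribing_game(phi = 0.5))
#' rep$dilemma$is_tragedy
#' @export
full_report <- function(params,
                        mutant_grid = seq(0, 1, length.out = 21),
                        epsilon_grid = 10^(-6:-1)) {
  params <- as_game(params)
  dilemma <- classify_dilemma(params)
  nash <- find_symmetric_nash(params)
  candidate <- if (!is.na(dilemma$dominant_strategy)) dilemma$dominant_strategy
               else if (nrow(nash) > 0L) nash$p_star[[1L]] else 1
  ess <- check_ess(candidate, params, mutant_grid = mutant_grid,
                   epsilon_grid = epsilon_grid)
  rest <- find_rest_points(params = params)
  structure(
    list(schema = "abxgame-report/1",
         parameters = unclass(params),
         dilemma = unclass(dilemma),
         nash = nash,
         ess = unclass(ess),
         rest_points = rest,
         cooperative_optimum = cooperative_optimum(params),
         peak_velocity = peak_velocity(params$phi)),
    class = "abx_report")
}

#' @export
print.abx_report <- function(x, ...) {
  print(structure(x$dilemma, class = "dilemma_report"))
  cat("\n")
  print(structure(x$ess, class = "ess_check"))
  cat("\nRest points:\n")
  print(x$rest_points$points)
  invisible(x)
}

#' Run manifest for reproducibility
#'
#' Records everything needed to reproduce a run: the effective parameters,
#' the command and flags, the seed, and the package version. Deterministic
#' outputs re-run under the same manifest are byte-identical; the
#' timestamp lives in the manifest only, never in data files.
#'
#' @param command subcommand or function name.
#' @param params an `abx_game`.
#' @param seed integer seed or `NULL`.
#' @param flags named list of effective options.
#' @param timestamp include a wall-clock timestamp (default `TRUE`).
#' @return A named list.
#' @export
run_manifest <- function(command, params, seed = NULL, flags = list(),
                         timestamp = TRUE) {
  params <- as_game(params)
  list(tool = "abxgame",
       version = as.character(utils::packageVersion("abxgame")),
       command = command,
       flags = flags,
       parameters = unclass(params),
       seed = seed,
       timestamp = if (timestamp)
         format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

#' Write a report as JSON
#'
#' Serializes with unboxed scalars and full numeric precision, so that the
#' file re-parses to the original values.
#'
#' @param x a list-like report.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  if (!is.data.frame(x)) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       dataframe = "columns")
  invisible(path)
}

#' Write a data frame as CSV
#'
#' Comma-separated, header row, '.' decimal, no locale formatting; numeric
#' columns printed with 12 significant digits, so values round-trip within
#' 1e-12 relative error.
#'
#' @param df a data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]]))
      out[[nm]] <- formatC(out[[nm]], digits = 12, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
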