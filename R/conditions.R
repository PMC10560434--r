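#' @keywords internal
#' Classed errors used across the package.
#'
#' Every user-facing failure carries a class of the form
#' `estuarch_<kind>` so callers (and tests) can dispatch on the kind of
#' contract violation rather than matching message text.
#' @noRd
est_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("estuarch_", class), "estuarch_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
est_invalid <- function(message) est_abort(message, "invalid_argument")

#' @noRd
est_key_error <- function(message) est_abort(message, "key_error")

#' @noRd
est_format_error <- function(message) est_abort(message, "format_error")

#' @noRd
est_empty_result <- function(message) est_abort(message, "empty_result")

#' @noRd
est_degenerate_fit <- function(message) est_abort(message, "degenerate_fit")

#' @noRd
est_fit_error <- function(message) est_abort(message, "fit_error")

#' @noRd
est_design_error <- function(message) est_abort(message, "design_error")

#' @noRd
est_undefined_correlation <- function(message) est_abort(message, "undefined_correlation")

#' Run an expression with a locally seeded RNG
#'
#' Restores the caller's RNG state afterwards so seeded package operations do
#' not perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
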