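#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a class so callers (and tests)
#' can distinguish validation problems from malformed files or I/O failures.
#' @noRd
sl_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "spotlink_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

sl_validation_error <- function(msg, ...) sl_stop("spotlink_validation_error", msg, ...)
sl_format_error     <- function(msg, ...) sl_stop("spotlink_format_error", msg, ...)
sl_parameter_error  <- function(msg, ...) sl_stop("spotlink_parameter_error", msg, ...)

#' Derive a stage seed from a root seed
#'
#' All randomness in a run flows from one root seed; each stage draws from a
#' deterministic offset so stages can be re-run in isolation. Kept below 2^31.
#' @noRd
sl_stage_seed <- function(seed, stage) {
  stages <- c(simulate = 11L, preprocess = 23L, de = 37L, gsea = 41L,
              regulon = 53L, aucell = 67L, signaling = 71L, scoring = 83L)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 97 + off) %% .Machine$integer.max)
}

#' Run an expression with a local RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
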