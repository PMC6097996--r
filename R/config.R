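#' Run configuration with published defaults
#'
#' Bundles the model constants and session settings an analysis run
#' needs. Every field has a default (the published difficulty
#' coefficients, a 25-item session, seed 1); a configuration file need
#' only state the fields it overrides, and the remainder fall back to
#' the defaults on load.
#'
#' @param coefficients A [difficulty_coefficients()] object.
#' @param session A [session_config()] object.
#' @param seed Master seed for simulation runs.
#' @param verbosity Logging level (0 silent, 1 messages).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(coefficients = difficulty_coefficients(),
                       session = session_config(),
                       seed = 1L, verbosity = 1L) {
  structure(list(coefficients = coefficients, session = session,
                 seed = as.integer(seed),
                 verbosity = as.integer(verbosity)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  print(x$coefficients)
  cat(sprintf("  session: %d items, first-item target %.3g, seed %d\n",
              x$session$test_length, x$session$first_item_difficulty,
              x$session$seed))
  cat(sprintf("  master seed %d, verbosity %d\n", x$seed, x$verbosity))
  invisible(x)
}

#' Write / read a run configuration as JSON
#'
#' The writer serialises every field; the reader accepts partial files
#' and fills unstated fields from the defaults, so configurations
#' round-trip losslessly and a minimal file stays minimal.
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   a `"run_config"`.
#' @export
write_config <- function(config, path) {
  payload <- list(
    coefficients = config$coefficients[c("intercept", "accuracy_effect",
                                         "direction_effect",
                                         "discrimination")],
    session = config$session[c("test_length", "first_item_difficulty",
                               "randomesque", "prior_mean", "prior_sd",
                               "seed")],
    seed = config$seed, verbosity = config$verbosity)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cf <- do.call(difficulty_coefficients,
                if (is.null(obj$coefficients)) list()
                else as.list(obj$coefficients))
  sc <- do.call(session_config,
                if (is.null(obj$session)) list()
                else as.list(obj$session))
  run_config(coefficients = cf, session = sc,
             seed = obj$seed %||% 1L,
             verbosity = obj$verbosity %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
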