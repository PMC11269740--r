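.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Pipeline logging
#'
#' Emits a timestamped message on the `message` stream when `level` is at or
#' above the threshold in `getOption("ssdscreen.log_level", "info")`. Every
#' pipeline stage logs input dimensions, filter outcomes and the seed in use
#' through this function so a run is auditable.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... Character fragments pasted into the message.
#' @return `invisible(NULL)`.
#' @export
ssd_log <- function(level = "info", ...) {
  level <- match.arg(level, names(.log_levels))
  threshold <- getOption("ssdscreen.log_level", "info")
  if (!threshold %in% names(.log_levels)) threshold <- "info"
  if (.log_levels[[level]] < .log_levels[[threshold]]) {
    return(invisible(NULL))
  }
  message(sprintf("[%s] %s", toupper(level), paste0(..., collapse = "")))
  invisible(NULL)
}

# classed conditions so callers/tests can distinguish failure modes
ssd_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ssd_error")))
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream;
# seed = NULL means "use the current stream as-is"
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# exact-string species matching after trimming whitespace and replacing
# internal spaces with underscores
normalize_species <- function(x) {
  gsub(" ", "_", trimws(as.character(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}
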