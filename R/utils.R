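# Internal helpers: conditions, logging, RNG scoping.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rxnemap <- function(msg, class) {
  stop(structure(
    class = c(class, "rxnemap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

integrity_error <- function(msg) stop_rxnemap(msg, "rxnemap_integrity_error")
format_error    <- function(msg) stop_rxnemap(msg, "rxnemap_format_error")
lookup_error    <- function(msg) stop_rxnemap(msg, "rxnemap_lookup_error")
unit_error      <- function(msg) stop_rxnemap(msg, "rxnemap_unit_error")
argument_error  <- function(msg) stop_rxnemap(msg, "rxnemap_argument_error")

#' Control diagnostic logging
#'
#' The pipeline emits structured progress and warning lines to standard error.
#' Logging is governed by `options(rxnemap.verbose = )`; it defaults to quiet
#' so that repeated programmatic runs stay silent.
#'
#' @param level one of "info" or "warn"
#' @param ... message parts, concatenated without separator
#' @return invisibly, the formatted message
#' @keywords internal
rx_log <- function(level = "info", ...) {
  msg <- paste0("[rxnemap ", level, "] ", paste0(..., collapse = ""))
  if (isTRUE(getOption("rxnemap.verbose", FALSE)) || identical(level, "warn")) {
    message(msg)
  }
  invisible(msg)
}

# Evaluate expr with a locally seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable alphabetical order independent of user locale
c_sort <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)))
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}
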