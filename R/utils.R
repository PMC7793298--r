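#' Derive stage seeds from a master seed
#'
#' Deterministically splits one master seed into named per-stage seeds so
#' that individual pipeline stages can be regenerated independently.  The
#' scheme is a simple splittable counter: seed_i = (master * 48271 + i)
#' mod (2^31 - 1), which keeps every derived seed a valid 32-bit integer.
#'
#' @param master single integer master seed.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds, one per stage.
#' @export
split_seed <- function(master, stages) {
  stopifnot(length(master) == 1L, is.finite(master))
  m <- 2147483647
  base <- (as.double(master) %% m) * 48271
  out <- vapply(seq_along(stages), function(i) {
    as.integer((base + i) %% m)
  }, integer(1))
  names(out) <- stages
  out
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# message-based log used by the standardization steps; quiet by default in
# tests (suppressMessages) but visible from the CLI
tg_log <- function(...) message("[trophoguild] ", ...)

#' @keywords internal
#' @noRd
assert_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", what, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
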