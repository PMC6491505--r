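`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Hierarchical seeding: a master seed deterministically yields per-subject
#' and per-stimulus seeds, so any single unit of a simulated dataset can be
#' regenerated in isolation. The result is always a valid 32-bit seed.
#'
#' @param master integer master seed.
#' @param index integer index of the child stream (subject, trial, ...).
#' @param salt optional extra integer to separate seed families.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index, salt = 0L) {
  stopifnot(is.numeric(master), is.numeric(index))
  as.integer((abs(master) %% 2147483647 * 7919 +
                abs(index) * 104729 + abs(salt) * 130363) %% 2147483647)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("'%s' must be a positive finite scalar", name)
  invisible(x)
}
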